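# Protease cleavage specificities, Keil-style P2/P1/P1' context rules.
# A bond after residue i is cut when: P1 (residue i) is in `p1` (empty = any),
# the P1' residue (i+1) is not in `p1prime_exclusions`, and, if `p2` is
# non-empty, the P2 residue (i-1) is in `p2`.
#
# These are the conventional BIOPEP-style formulations; edit or extend this
# file (or supply your own via read_enzyme_rules) to match a specific release.
# (Residue letters are quoted: bare Y/N are YAML 1.1 booleans.)
trypsin:
  p1: ["K", "R"]
  p1prime_exclusions: ["P"]
  p2: []
papain:
  p1: []
  p1prime_exclusions: ["P"]
  p2: ["A", "V", "L", "I", "F", "W", "Y"]
pepsin_ph2:
  p1: ["F", "L", "W", "Y"]
  p1prime_exclusions: ["P"]
  p2: []
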