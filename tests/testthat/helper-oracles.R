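# Independent oracles and small utilities shared across tests.

# Brute-force cleavage oracle: tests every bond of the sequence against every
# rule's P2/P1/P1' predicate with plain scalar logic (no vectorization shared
# with the implementation).
brute_force_sites <- function(sequence, rules) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (inherits(rules, "cleavage_rule")) rules <- list(rules)
  sites <- integer(0)
  for (i in seq_len(length(chars) - 1L)) {
    for (r in rules) {
      p1_ok <- length(r$p1) == 0L || chars[i] %in% r$p1
      p1p_ok <- !(chars[i + 1L] %in% r$p1prime_exclusions)
      p2_ok <- length(r$p2) == 0L || (i > 1L && chars[i - 1L] %in% r$p2)
      if (p1_ok && p1p_ok && p2_ok) {
        sites <- c(sites, i)
        break
      }
    }
  }
  sites
}

random_aa_sequence <- function(len) {
  paste(sample(aa_alphabet(), len, replace = TRUE), collapse = "")
}

cosine_similarity <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# Random peptide that trypsin releases cleanly when planted after a K
# separator: no internal K/R, no proline start, K terminus.
random_tryptic_peptide <- function(len) {
  body <- sample(setdiff(aa_alphabet(), c("K", "R", "P")), len - 1L,
                 replace = TRUE)
  first <- sample(setdiff(aa_alphabet(), c("K", "R", "P")), 1L)
  body[1L] <- first
  paste(c(body, "K"), collapse = "")
}
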