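peptide,ic50_pre_uM,sd_pre,ic50_post_uM,sd_post,n_replicates
IPYADFK,0.63,0.09,0.80,0.08,3
LYDHLGK,9.41,0.24,24.34,0.29,3
INEMLDTK,6.53,0.21,15.65,0.15,3
IHFGTTGK,5.34,0.15,33.73,0.23,3
NWPWMK,6.23,0.34,7.27,0.17,3
FYEPFM,10.26,0.21,11.41,0.43,3
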