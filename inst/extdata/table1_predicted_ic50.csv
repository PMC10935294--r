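peptide,predicted_ic50_uM,length,note
TVK,205.63,3,
TIR,219.84,3,
YNL,43.40,3,previously reported ACE/renin-inhibitory tripeptide
EAEFQK,416.43,6,
FYEPFM,9.53,6,
SFTNVK,52.93,6,
LEGDLK,233.12,6,
NWPWMK,8.19,6,
IPYADFK,0.64,7,
SIHEIEK,23.51,7,
LQDLVDK,112.97,7,
VDYNIIG,15.26,7,
NLEVAVK,11.29,7,
TEELEEAK,12.74,8,
LYDQHLGK,3.25,8,alternate 7-residue spelling LYDHLGK used in assay tables; kept verbatim here
VLDTEEER,16.77,8,
IHFGTTGK,7.87,8,
AALEQTER,37.25,8,
INEMLDTK,1.82,8,
DEEMEQIK,30.98,8,
ELEEISER,56.22,8,
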