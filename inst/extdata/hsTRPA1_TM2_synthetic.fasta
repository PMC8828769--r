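>hsTRPA1_TM2_synthetic region=761-820 offset=760 | SYNTHETIC stand-in for the human TRPA1 TM2 neighbourhood (real RefSeq/UniProt sequence not bundled); carries a CRAC motif whose central tyrosine maps to full-protein residue 785
SGAGFAGMTWAGSIAGMAWGLAGAYAGRAGSTAGFMAWGASTAGMFAWGSAGTAGSIMAG
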