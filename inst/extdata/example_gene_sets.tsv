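gene	tier	inheritance
HDAC4	E	AD
CACNA1E	E	AD
GRM7	S	AR
KMT2E	S	AD
SOX5	S	AD
SHROOM4	S	XLR
WWOX	S	AR
SCN1A	E	AD
STXBP1	E	AD
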