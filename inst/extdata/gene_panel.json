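["ATP1A2", "CACNA1A", "CSNK1D", "KCNK18", "NOTCH3",
 "PNKD", "PRRT2", "SCN1A", "SLC1A3", "TREX1"]
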