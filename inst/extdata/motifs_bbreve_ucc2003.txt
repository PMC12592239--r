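# Restriction-modification recognition motifs of B. breve UCC2003 (IUPAC).
# This set is closed under reverse complementation.
CTGCAG
RTCGAY
GGCGCC
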