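# Sth1 dCas9 consensus PAM (3' of the protospacer), IUPAC.
# Relaxed PAM variants tolerated by Sth1 dCas9 are strain/reference specific:
# append them here (one pattern per line, same length) to scan with a
# relaxed set.
NNAGAAW
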