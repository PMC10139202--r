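# Synthetic stand-in panel of autism-candidate TF symbols used in examples
# and tests (NOT the curated SFARI list; constructed for demonstration).
NR2F1
VDR
NR4A2
NR1D1
RORA
SATB1
ARNT2
AR
TCF7L2
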