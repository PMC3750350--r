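# AFLP enzyme catalogue: name, recognition site, cut offset (bases 5' of the
# cut within the recognition occurrence, top strand)
EcoRI GAATTC 1
MseI  TTAA   1
BsmI  GAATGC 6
TaqI  TCGA   1
SacI  GAGCTC 5
HpaII CCGG   1
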