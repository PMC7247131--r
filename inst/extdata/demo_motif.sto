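# STOCKHOLM 1.0
#=GF ID demo-leader
#=GF CC Hand-built demonstration alignment with compensatory variation in a
#=GF CC single hairpin; not a biological motif.
seq1/1-15    GGAUGAAUCGCAUCC
seq2/1-15    GGAUGAAUCGCAUCC
seq3/1-15    CAAUGAGUCGCAUUG
seq4/1-15    CAGCAAAUCGUGCUG
seq5/1-15    UUGCAAAUCGUGCAA
seq6/1-15    UUGCAAGUCGUGCAA
seq7/1-15    ACUGGAAUCGCUAGU
seq8/1-15    ACUAGAAUCGCUAGU
#=GC SS_cons <<<<<.....>>>>>
//
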