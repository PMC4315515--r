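>synthetic_wt_allele_amplicon synthetic 286 bp exon-3-like amplicon; one constitutive EcoRI site (fragments 207+79)
GGGGAAAAGGCAAGAGGGGCGCGGGTCCCAGAGGCAGGCGCACTGATCTCTTGATTGTGCCACTCGGTGCCTCTTGCTCTTCTGTAAAGTCACCCACCTCTTACTCCTTCGCAGCAAGAAAGGGAGGGAAATCACGCAAGGCCTCTGGCGCAAAGCGTACCTATATCCACTGACTTTCACGAATATTTCTTACTATGACAATTTTAGAATTCAGTCAGAAGCCTCACGCTGGTATCTCAGACACATAAAGCACCATAGGTGGAGAAATGGGTACGGACAAGGACGA
>synthetic_mutant_allele_amplicon synthetic 286 bp amplicon; A>T creates allele-specific EcoRI site (fragments 128+79+79)
GGGGAAAAGGCAAGAGGGGCGCGGGTCCCAGAGGCAGGCGCACTGATCTCTTGATTGTGCCACTCGGTGCCTCTTGCTCTTCTGTAAAGTCACCCACCTCTTACTCCTTCGCAGCAAGAAAGGGAGGGAATTCACGCAAGGCCTCTGGCGCAAAGCGTACCTATATCCACTGACTTTCACGAATATTTCTTACTATGACAATTTTAGAATTCAGTCAGAAGCCTCACGCTGGTATCTCAGACACATAAAGCACCATAGGTGGAGAAATGGGTACGGACAAGGACGA
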