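file,md5
table1_reference.csv,6408dcebdb3fa323dd4cddafa9410397
table2_probabilities.csv,42e5d9e21fbf504f3c941e80cdf366d3
transitions_single.csv,4060564cf45cb6f07c15112e772095e6
transitions_accumulated.csv,54a4d8673f2da3d911f2a1b34e15a1c4
abundance_approx_synthetic.csv,4a09a4710c14e140c1b73220c2bae8bd
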