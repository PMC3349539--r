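motif,abundance,source
C1,0.46,ecoli_approx_synthetic
C2,0.04,ecoli_approx_synthetic
C3,0.02,ecoli_approx_synthetic
C4,0.01,ecoli_approx_synthetic
I1,0.35,ecoli_approx_synthetic
I2,0.03,ecoli_approx_synthetic
I3,0.02,ecoli_approx_synthetic
I4,0.07,ecoli_approx_synthetic
C1,0.39,yeast_approx_synthetic
C2,0.06,yeast_approx_synthetic
C3,0.03,yeast_approx_synthetic
C4,0.02,yeast_approx_synthetic
I1,0.28,yeast_approx_synthetic
I2,0.08,yeast_approx_synthetic
I3,0.05,yeast_approx_synthetic
I4,0.09,yeast_approx_synthetic
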