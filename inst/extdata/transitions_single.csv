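motif,from,G+,G-,P+T+,P+T-,P-T-,P-T+
C1,G+,0.251,0.000,0.008,0.000,0.000,0.000
C1,G-,0.000,0.329,0.000,0.003,0.000,0.000
C1,P+T+,0.015,0.000,0.180,0.000,0.013,0.000
C1,P+T-,0.0000,0.0049,0.0000,0.0310,0.0000,0.0000
C1,P-T-,0.000,0.000,0.015,0.000,0.157,0.000
C1,P-T+,0,0,0,0,0,0
C2,G+,0.000,0.000,0.007,0.000,0.000,0.000
C2,G-,0.000,0.820,0.000,0.007,0.000,0.000
C2,P+T+,0.008,0.000,0.022,0.000,0.001,0.000
C2,P+T-,0.000,0.007,0.000,0.039,0.000,0.000
C2,P-T-,0.000,0.000,0.043,0.000,0.039,0.000
C2,P-T+,0,0,0,0,0,0
C3,G+,0.317,0.000,0.008,0.000,0.000,0.000
C3,G-,0.000,0.242,0.000,0.026,0.000,0.000
C3,P+T+,0.023,0.000,0.030,0.000,0.000,0.000
C3,P+T-,0.000,0.043,0.000,0.174,0.000,0.046
C3,P-T-,0,0,0,0,0,0
C3,P-T+,0.000,0.000,0.000,0.046,0.000,0.151
C4,G+,0.815,0.000,0.019,0.000,0.000,0.000
C4,G-,0.000,0.000,0.000,0.019,0.000,0.000
C4,P+T+,0.000,0.000,0.037,0.000,0.000,0.000
C4,P+T-,0.000,0.037,0.000,0.037,0.000,0.000
C4,P-T-,0,0,0,0,0,0
C4,P-T+,0.000,0.000,0.000,0.000,0.000,0.037
I1,G+,0.241,0.000,0.069,0.000,0.000,0.000
I1,G-,0.000,0.103,0.000,0.000,0.000,0.000
I1,P+T+,0.000,0.000,0.345,0.000,0.000,0.000
I1,P+T-,0,0,0,0,0,0
I1,P-T-,0.000,0.000,0.000,0.000,0.241,0.000
I1,P-T+,0,0,0,0,0,0
I2,G+,0.144,0.000,0.024,0.000,0.000,0.000
I2,G-,0.000,0.408,0.000,0.016,0.000,0.000
I2,P+T+,0.00,0.00,0.16,0.00,0.00,0.00
I2,P+T-,0.000,0.032,0.000,0.080,0.000,0.000
I2,P-T-,0.000,0.000,0.000,0.000,0.128,0.000
I2,P-T+,0.000,0.000,0.000,0.000,0.000,0.008
I3,G+,0.091,0.000,0.000,0.000,0.000,0.000
I3,G-,0.000,0.212,0.000,0.061,0.000,0.000
I3,P+T+,0,0,0,0,0,0
I3,P+T-,0.000,0.121,0.000,0.394,0.000,0.000
I3,P-T-,0,0,0,0,0,0
I3,P-T+,0.000,0.000,0.000,0.000,0.000,0.121
I4,G+,0.398,0.000,0.008,0.000,0.000,0.000
I4,G-,0.000,0.141,0.000,0.023,0.000,0.000
I4,P+T+,0.000,0.000,0.063,0.000,0.000,0.000
I4,P+T-,0.000,0.047,0.000,0.156,0.000,0.000
I4,P-T-,0.000,0.000,0.000,0.000,0.008,0.000
I4,P-T+,0.000,0.000,0.000,0.000,0.000,0.156
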