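motif,from,G+,G-,P+T+,P+T-,P-T-,P-T+
C1,G+,0.212,0.000,0.082,0.000,0.071,0.000
C1,G-,0.000,0.235,0.000,0.010,0.000,0.000
C1,P+T+,0.035,0.000,0.113,0.000,0.052,0.000
C1,P+T-,0.000,0.020,0.000,0.007,0.000,0.000
C1,P-T-,0.030,0.000,0.052,0.000,0.082,0.000
C1,P-T+,0,0,0,0,0,0
C2,G+,0.005,0.000,0.008,0.000,0.006,0.000
C2,G-,0.000,0.822,0.000,0.018,0.000,0.000
C2,P+T+,0.006,0.000,0.013,0.000,0.011,0.000
C2,P+T-,0.000,0.056,0.000,0.016,0.000,0.000
C2,P-T-,0.008,0.000,0.014,0.000,0.018,0.000
C2,P-T+,0,0,0,0,0,0
C3,G+,0.247,0.000,0.026,0.000,0.000,0.000
C3,G-,0.000,0.222,0.000,0.050,0.000,0.043
C3,P+T+,0.016,0.000,0.008,0.000,0.000,0.000
C3,P+T-,0.000,0.100,0.000,0.118,0.000,0.000
C3,P-T-,0,0,0,0,0,0
C3,P-T+,0.000,0.086,0.000,0.000,0.000,0.086
C4,G+,0.825,0.000,0.069,0.000,0.000,0.000
C4,G-,0.000,0.000,0.000,0.005,0.000,0.005
C4,P+T+,0.042,0.000,0.011,0.000,0.000,0.000
C4,P+T-,0.000,0.011,0.000,0.011,0.000,0.000
C4,P-T-,0,0,0,0,0,0
C4,P-T+,0.000,0.011,0.000,0.000,0.000,0.011
I1,G+,0.171,0.000,0.114,0.000,0.086,0.000
I1,G-,0.000,0.024,0.000,0.000,0.000,0.000
I1,P+T+,0.033,0.000,0.229,0.000,0.098,0.000
I1,P+T-,0,0,0,0,0,0
I1,P-T-,0.024,0.000,0.098,0.000,0.122,0.000
I1,P-T+,0,0,0,0,0,0
I2,G+,0.088,0.000,0.048,0.000,0.040,0.000
I2,G-,0.000,0.398,0.000,0.029,0.007,0.007
I2,P+T+,0.016,0.000,0.088,0.000,0.040,0.000
I2,P+T-,0.000,0.058,0.000,0.037,0.000,0.000
I2,P-T-,0.013,0.015,0.040,0.000,0.061,0.000
I2,P-T+,0.000,0.015,0.000,0.000,0.000,0.001
I3,G+,0.024,0.000,0.000,0.000,0.000,0.000
I3,G-,0.000,0.165,0.000,0.098,0.000,0.039
I3,P+T+,0,0,0,0,0,0
I3,P+T-,0.000,0.196,0.000,0.353,0.000,0.000
I3,P-T-,0,0,0,0,0,0
I3,P-T+,0.000,0.078,0.000,0.000,0.000,0.047
I4,G+,0.401,0.000,0.033,0.000,0.017,0.000
I4,G-,0.000,0.088,0.000,0.032,0.000,0.032
I4,P+T+,0.037,0.000,0.035,0.000,0.005,0.000
I4,P+T-,0.000,0.064,0.000,0.088,0.000,0.000
I4,P-T-,0.009,0.000,0.003,0.000,0.001,0.000
I4,P-T+,0.000,0.064,0.000,0.000,0.000,0.088
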