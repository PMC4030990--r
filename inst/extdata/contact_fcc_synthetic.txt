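# SYNTHETIC pairwise contact-energy matrix (arbitrary units).
# A stand-in for a published FCC-lattice contact potential: entries are
# e_uv = -(0.8 + 2.8 * s_u * s_v) with s the min-max-scaled Kyte-Doolittle
# hydropathy, rounded to 2 decimals. These are NOT values from any
# publication; they only provide a hydrophobicity-structured, symmetric
# matrix so the FCC contact-model pipeline can be exercised end to end.
C M F I L V W Y A G T S N Q D E H R K P
C -2.49
M -2.35 -2.22
F -2.57 -2.42 -2.64
I -2.98 -2.79 -3.07 -3.60
L -2.81 -2.64 -2.89 -3.38 -3.18
V -2.91 -2.72 -3.00 -3.51 -3.30 -3.42
W -1.67 -1.60 -1.71 -1.92 -1.83 -1.88 -1.25
Y -1.57 -1.51 -1.61 -1.80 -1.72 -1.76 -1.20 -1.15
A -2.32 -2.19 -2.39 -2.76 -2.61 -2.69 -1.58 -1.50 -2.17
G -1.79 -1.71 -1.83 -2.08 -1.98 -2.03 -1.31 -1.25 -1.69 -1.38
T -1.72 -1.64 -1.76 -1.98 -1.89 -1.94 -1.27 -1.22 -1.63 -1.34 -1.30
S -1.70 -1.62 -1.73 -1.95 -1.86 -1.91 -1.26 -1.21 -1.61 -1.32 -1.29 -1.27
N -1.04 -1.02 -1.05 -1.11 -1.09 -1.10 -0.92 -0.91 -1.02 -0.94 -0.93 -0.93 -0.83
Q -1.04 -1.02 -1.05 -1.11 -1.09 -1.10 -0.92 -0.91 -1.02 -0.94 -0.93 -0.93 -0.83 -0.83
D -1.04 -1.02 -1.05 -1.11 -1.09 -1.10 -0.92 -0.91 -1.02 -0.94 -0.93 -0.93 -0.83 -0.83 -0.83
E -1.04 -1.02 -1.05 -1.11 -1.09 -1.10 -0.92 -0.91 -1.02 -0.94 -0.93 -0.93 -0.83 -0.83 -0.83 -0.83
H -1.11 -1.09 -1.13 -1.20 -1.17 -1.19 -0.96 -0.94 -1.08 -0.98 -0.97 -0.97 -0.84 -0.84 -0.84 -0.84 -0.86
R -0.80 -0.80 -0.80 -0.80 -0.80 -0.80 -0.80 -0.80 -0.80 -0.80 -0.80 -0.80 -0.80 -0.80 -0.80 -0.80 -0.80 -0.80
K -0.95 -0.93 -0.95 -0.99 -0.97 -0.98 -0.87 -0.87 -0.93 -0.89 -0.88 -0.88 -0.82 -0.82 -0.82 -0.82 -0.83 -0.80 -0.81
P -1.50 -1.44 -1.53 -1.70 -1.63 -1.67 -1.16 -1.12 -1.43 -1.21 -1.18 -1.17 -0.90 -0.90 -0.90 -0.90 -0.93 -0.80 -0.86 -1.09
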