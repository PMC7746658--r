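disease_no,exp1_recall,exp1_precision,exp1_f1,exp2_recall,exp2_precision,exp2_f1,exp3_recall,exp3_precision,exp3_f1,exp4_recall,exp4_precision,exp4_f1
1,0.17,0.89,0.29,0.48,0.54,0.51,0.33,0.88,0.48,0.46,0.60,0.52
2,0.59,0.61,0.60,0.86,0.77,0.81,0.66,0.84,0.74,0.93,0.72,0.81
3,0.37,0.41,0.39,0.50,0.88,0.64,0.70,0.75,0.72,0.30,0.56,0.39
4,0.41,0.85,0.55,0.88,0.43,0.58,0.43,0.93,0.59,0.71,0.96,0.82
5,0.50,0.42,0.46,0.69,0.56,0.62,0.47,0.68,0.56,0.56,0.72,0.63
6,0.53,0.80,0.64,0.89,0.90,0.89,0.96,0.73,0.83,0.92,0.86,0.89
7,0.87,0.65,0.75,0.78,0.76,0.77,0.61,0.91,0.73,0.81,0.79,0.80
8,0.28,0.40,0.33,0.94,0.45,0.61,0.69,0.87,0.77,0.74,0.69,0.71
9,0.92,0.55,0.69,0.67,0.85,0.75,0.91,0.91,0.91,0.91,0.91,0.91
10,0.51,0.84,0.63,0.62,0.95,0.75,0.58,0.91,0.71,0.60,0.98,0.74
11,0.96,0.66,0.78,0.93,0.98,0.95,0.96,0.95,0.96,0.99,0.97,0.98
12,0.66,0.93,0.77,0.95,0.64,0.77,0.90,0.90,0.90,0.95,0.80,0.87
13,0.73,0.43,0.54,0.85,0.55,0.67,0.81,0.71,0.76,0.93,0.53,0.68
14,0.52,0.75,0.61,0.84,0.65,0.74,0.35,0.93,0.50,0.89,0.94,0.91
15,0.12,0.78,0.21,0.79,0.54,0.64,0.72,0.95,0.82,0.69,0.89,0.78
16,0.57,0.98,0.72,0.94,0.88,0.91,0.94,0.82,0.88,0.86,0.97,0.91
17,0.88,0.78,0.83,0.71,0.63,0.67,0.86,0.84,0.85,0.89,0.75,0.82
18,0.28,0.62,0.38,0.62,0.86,0.72,0.84,0.79,0.81,0.66,0.98,0.79
19,0.22,0.65,0.32,0.53,0.52,0.52,0.76,0.57,0.65,0.62,0.66,0.64
20,0.43,0.59,0.50,0.62,0.73,0.67,0.67,0.77,0.72,0.70,0.75,0.73
21,0.29,0.54,0.37,0.54,0.78,0.64,0.81,0.92,0.86,0.81,0.70,0.75
22,0.65,0.57,0.61,0.52,0.89,0.66,0.94,0.52,0.67,0.76,0.70,0.73
23,0.54,0.67,0.60,0.63,0.82,0.71,0.58,0.97,0.73,0.72,0.92,0.81
24,0.60,0.45,0.52,0.31,0.73,0.44,0.93,0.53,0.67,0.81,0.67,0.73
25,0.95,0.74,0.83,0.89,0.98,0.94,0.97,0.89,0.92,0.99,0.97,0.98
26,0.88,0.62,0.73,0.92,1.00,0.96,0.85,0.92,0.88,0.92,0.80,0.86
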