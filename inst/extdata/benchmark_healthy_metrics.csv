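species,exp1_recall,exp1_precision,exp1_f1,exp2_recall,exp2_precision,exp2_f1,exp3_recall,exp3_precision,exp3_f1,exp4_recall,exp4_precision,exp4_f1
Apple,0.37,0.72,0.49,0.93,1.00,0.96,0.81,0.92,0.86,0.89,0.94,0.91
Blueberry,0.44,0.74,0.55,0.91,1.00,0.95,0.76,0.97,0.85,0.84,0.80,0.82
Cherry,0.74,0.35,0.48,0.88,0.97,0.92,0.97,0.71,0.82,0.92,0.84,0.88
Corn,0.67,0.72,0.69,1.00,0.97,0.98,0.99,0.89,0.94,0.91,1.00,0.95
Grape,0.65,0.50,0.57,0.74,0.93,0.82,0.81,0.62,0.70,0.77,0.71,0.74
Peach,0.42,0.55,0.48,0.96,0.71,0.82,0.88,0.82,0.85,0.65,0.94,0.77
Pepper,0.73,0.17,0.28,0.79,0.83,0.81,0.86,0.68,0.76,0.94,0.80,0.86
Potato,0.13,0.22,0.16,0.13,0.67,0.22,0.40,1.00,0.57,0.53,0.47,0.50
Raspberry,0.37,0.76,0.50,0.90,0.68,0.77,0.27,1.00,0.43,0.80,0.85,0.82
Soybean,0.44,0.77,0.56,0.98,0.99,0.98,0.94,0.92,0.93,0.92,0.86,0.89
Strawberry,0.15,0.38,0.22,0.53,0.78,0.63,0.80,0.71,0.75,0.60,0.80,0.69
Tomato,0.54,0.70,0.61,0.85,0.92,0.88,0.86,0.97,0.91,0.86,0.97,0.91
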