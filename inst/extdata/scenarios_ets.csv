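scenario,dose,p_grade01,p_grade2,p_grade3,p_grade4,is_mtd
1,1,0.83,0.12,0.04,0.01,0
1,2,0.75,0.15,0.07,0.03,0
1,3,0.62,0.18,0.11,0.09,0
1,4,0.51,0.19,0.14,0.16,1
1,5,0.34,0.16,0.15,0.35,0
1,6,0.19,0.11,0.11,0.59,0
2,1,0.92,0.03,0.03,0.02,0
2,2,0.85,0.05,0.07,0.03,0
2,3,0.7,0.1,0.14,0.06,0
2,4,0.55,0.15,0.21,0.09,1
2,5,0.24,0.26,0.35,0.15,0
2,6,0,0.36,0.49,0.21,0
3,1,0.78,0.14,0.06,0.02,0
3,2,0.56,0.19,0.12,0.12,1
3,3,0.5,0.18,0.14,0.18,0
3,4,0.4,0.17,0.15,0.28,0
3,5,0.3,0.15,0.14,0.41,0
3,6,0.16,0.09,0.1,0.65,0
4,1,0.88,0.04,0.06,0.02,0
4,2,0.64,0.12,0.17,0.07,0
4,3,0.52,0.16,0.22,0.1,1
4,4,0.35,0.22,0.3,0.13,0
4,5,0.17,0.28,0.38,0.17,0
4,6,0,0.39,0.52,0.23,0
5,1,1,0,0,0,0
5,2,0.91,0.06,0.03,0,0
5,3,0.88,0.07,0.04,0.01,0
5,4,0.86,0.08,0.05,0.01,0
5,5,0.8,0.1,0.08,0.02,0
5,6,0.65,0.13,0.14,0.08,1
6,1,0.5,0.25,0.11,0.14,1
6,2,0.38,0.24,0.12,0.26,0
6,3,0.29,0.21,0.12,0.38,0
6,4,0.19,0.16,0.1,0.55,0
6,5,0.13,0.11,0.08,0.68,0
6,6,0.08,0.07,0.05,0.8,0
7,1,0.78,0.14,0,0.08,0
7,2,0.58,0.18,0,0.24,1
7,3,0.5,0.18,0,0.32,0
7,4,0.4,0.17,0,0.43,0
7,5,0.3,0.15,0,0.55,0
7,6,0.16,0.09,0,0.75,0
8,1,0.92,0,0.08,0,0
8,2,0.76,0,0.24,0,0
8,3,0.68,0,0.32,0,0
8,4,0.57,0,0.43,0,1
8,5,0.45,0,0.55,0,0
8,6,0.25,0,0.75,0,0
9,1,0.66,0.34,0,0,0
9,2,0.1,0.9,0,0,1
9,3,0,0.86,0.14,0,0
9,4,0,0.54,0.46,0,0
9,5,0,0.2,0.8,0,0
9,6,0,0.33,0,0.67,0
10,1,0.84,0.16,0,0,0
10,2,0.52,0.48,0,0,0
10,3,0.36,0.64,0,0,0
10,4,0.14,0.86,0,0,1
10,5,0.45,0,0.55,0,0
10,6,0.25,0,0.75,0,0
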