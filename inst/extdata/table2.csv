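sample_no,gc_total,gc_prop,gc_but,ann_total,ann_prop,ann_but,u_total,u_prop,u_but,dev_total,dev_prop,dev_but
1,7.54,1.53,1.25,7.50,1.58,1.26,0.68,0.12,0.09,0.5,-3.3,-0.8
2,2.46,0.78,0.23,2.40,0.76,0.23,0.18,0.05,0.01,0.4,2.6,0.0
3,4.00,1.29,0.43,4.07,1.34,0.44,0.31,0.10,0.03,-1.8,-3.9,-2.3
4,21.32,3.93,3.53,21.27,3.90,3.54,1.84,0.27,0.25,0.2,0.8,-0.3
5,5.48,1.47,0.70,5.57,1.45,0.69,0.42,0.11,0.04,-1.6,1.4,1.4
6,5.07,1.96,0.33,5.07,1.99,0.32,0.38,0.15,0.02,0.0,-1.5,3.0
7,8.32,2.22,1.28,8.61,2.25,1.25,0.74,0.18,0.09,-3.5,-1.4,2.3
8,4.49,1.50,0.49,4.87,1.50,0.48,0.36,0.11,0.03,-8.5,0.0,2.0
9,9.35,2.88,1.25,9.38,2.86,1.23,0.79,0.21,0.10,-0.3,0.7,1.6
10,9.05,1.85,0.81,8.45,1.80,0.82,0.62,0.14,0.06,6.6,2.7,-1.2
11,6.02,1.61,0.44,5.98,1.60,0.40,0.45,0.12,0.03,0.7,0.6,9.1
12,7.00,1.68,0.92,7.49,1.67,0.88,0.58,0.12,0.06,-7.0,0.6,4.3
13,6.79,1.97,1.03,6.96,2.00,0.95,0.51,0.16,0.07,-2.5,-1.5,7.8
14,1.32,0.37,0.10,1.27,0.34,0.08,0.09,0.02,0.01,3.8,8.1,20.0
15,6.22,0.58,0.94,6.06,0.45,0.92,0.43,0.03,0.06,2.6,22.4,2.1
16,6.73,2.82,0.27,6.66,2.86,0.29,0.48,0.22,0.02,1.0,-1.4,-7.4
17,5.32,1.26,0.34,5.42,1.30,0.35,0.41,0.09,0.02,-1.9,-3.2,-2.9
18,9.66,2.37,1.24,9.27,2.34,1.18,0.81,0.17,0.08,4.0,1.3,4.8
19,5.64,1.38,0.29,5.62,1.47,0.30,0.39,0.11,0.02,0.4,-6.5,-3.4
20,2.77,0.61,0.29,2.82,0.58,0.30,0.21,0.04,0.02,-1.8,4.9,-3.4
21,10.40,3.49,0.55,10.49,3.35,0.54,0.88,0.26,0.04,-0.9,4.0,1.8
22,3.06,0.86,0.47,3.16,0.86,0.44,0.24,0.06,0.03,-3.3,0.0,6.4
23,4.87,1.08,0.65,4.87,1.06,0.65,0.37,0.08,0.05,0.0,1.9,0.0
24,2.85,0.71,0.29,2.78,0.68,0.30,0.20,0.05,0.02,2.5,4.2,-3.4
25,7.55,2.03,0.79,7.62,2.00,0.76,0.59,0.15,0.05,-0.9,1.5,3.8
26,5.97,0.94,0.56,5.68,0.90,0.56,0.42,0.07,0.04,4.9,4.3,0.0
27,6.41,1.71,1.09,6.38,1.64,1.09,0.51,0.12,0.08,0.5,4.1,0.0
28,5.33,1.05,0.94,5.43,1.07,0.90,0.38,0.08,0.06,-1.9,-1.9,4.3
29,9.07,1.80,1.15,8.96,1.67,1.08,0.72,0.13,0.08,1.2,7.2,6.1
30,9.37,3.33,0.87,9.42,3.35,0.84,0.83,0.24,0.06,-0.5,-0.6,3.4
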