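clip_id,valence_mean,valence_sd,arousal_mean,arousal_sd,dominance_mean,dominance_sd
1,6.87,0.92,5.60,1.68,6.67,1.23
2,6.47,0.99,4.87,1.88,7.00,0.76
3,4.73,1.49,6.53,1.30,6.13,1.51
4,5.33,1.18,5.80,2.01,6.47,1.19
5,6.93,0.70,6.60,1.30,5.40,1.92
6,7.00,1.00,4.87,1.46,5.93,1.53
7,6.20,1.15,2.73,1.75,6.93,1.39
8,5.60,0.74,3.73,1.39,6.67,1.40
9,3.27,1.39,5.87,1.36,4.53,1.68
10,4.20,1.08,3.80,1.74,6.20,1.47
11,5.47,2.26,5.53,1.55,5.40,1.92
12,2.67,1.40,7.60,0.99,3.40,1.18
13,3.60,0.99,6.13,1.73,4.27,1.53
14,3.40,0.91,7.20,1.32,3.93,1.91
15,2.87,0.92,5.07,1.58,4.67,1.63
16,2.93,1.03,4.87,1.51,4.80,2.11
17,4.27,1.10,3.87,2.03,6.07,1.71
18,4.47,1.13,6.07,2.22,5.40,1.64
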