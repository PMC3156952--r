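population	group	n_ind	n_full	lat	lon	h_ref
Brahmin	india	23	23	17.69	83.22	60.02
GIH	india	24	60	23.03	72.58	60.96
Irula	india	23	23	17.69	83.22	95.12
Mala_Madiga	india	24	24	17.69	83.22	89.33
Yadava	india	22	22	17.69	83.22	92.82
LWK	africa	24	82	0.62	34.77	85.81
YRI	africa	24	82	7.39	3.90	76.86
CEU	europe	24	81	48.86	2.35	77.68
TSI	europe	24	81	43.77	11.25	72.54
CHB	eastasia	24	81	39.91	116.40	78.88
CHD	eastasia	24	81	39.91	116.40	72.34
JPT	eastasia	24	82	35.68	139.69	62.88
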