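construct	divergence_pct	colonies_mean	colonies_se
0%	0	1164	34
0.7%	0.7	822	25
3%	3	209	39
5%	5	77	8
10%	10	50	6
15%	15	334	52
20%	20	267	46
30%	30	195	16
75%_scrambled	75	21	6
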