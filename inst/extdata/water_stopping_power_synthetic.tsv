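energy_eV	let_eV_per_nm
1000	12.6
1500	9.6
2000	7.8
3000	5.75
4000	4.6
5000	3.9
6000	3.4
8000	2.7
10000	2.256
15000	1.61
20000	1.317
30000	0.9653
40000	0.7777
50000	0.6603
60000	0.5797
80000	0.4757
100000	0.4115
150000	0.3238
200000	0.2793
300000	0.2355
400000	0.2148
500000	0.2034
600000	0.1963
800000	0.1886
1000000	0.1849
1250000	0.1829
1500000	0.1822
2000000	0.1824
3000000	0.1846
4000000	0.187
5000000	0.1892
6000000	0.1911
8000000	0.1943
10000000	0.1968
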