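label	oxygen_percent	BD	SSB	SSBp	2SSB	DSB	DSBp	DSBpp	total_SSB	total_DSB	total_damage
Titanium K-shell	21	365.0	160.7	13.3	3.1	7.7	2.2	0.8	177.1	10.7	552.8
Aluminum K-shell	21	257.8	129.8	18.7	6.1	9.4	4.1	2.3	154.6	15.9	428.3
Copper L-shell	21	207.8	114.8	19.9	7.2	10.1	5.1	3.2	141.9	18.5	368.2
Carbon K-shell	21	160.5	99.0	35.6	14.3	16.3	9.4	6.9	127.3	21.2	309.0
Co-60	21	424.4	178.6	8.0	1.0	7.1	1.0	0.1	187.4	8.1	620.2
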