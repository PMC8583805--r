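label	oxygen_percent	BD	SSB	SSBp	2SSB	DSB	DSBp	DSBpp	total_SSB	total_DSB	total_damage
Titanium K-shell	0.1	289.4	116.0	6.6	1.3	3.8	0.9	0.3	123.8	4.9	418.1
Aluminum K-shell	0.1	235.7	105.5	11.5	3.2	5.7	2.0	1.0	120.3	8.7	364.6
Copper L-shell	0.1	206.5	101.1	13.9	4.4	7.0	3.0	1.6	119.5	11.5	337.5
Carbon K-shell	0.1	170.9	95.0	30.0	10.8	14.5	7.3	4.5	117.4	15.5	303.8
Co-60	0.1	317.2	123.2	3.4	0.3	3.2	0.3	0.0	127.0	3.5	447.5
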