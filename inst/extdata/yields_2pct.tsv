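label	oxygen_percent	BD	SSB	SSBp	2SSB	DSB	DSBp	DSBpp	total_SSB	total_DSB	total_damage
Titanium K-shell	2	350.8	151.0	11.5	2.6	6.7	1.8	0.7	165.1	9.1	525.0
Aluminum K-shell	2	255.5	125.2	17.1	5.4	8.6	3.6	1.9	147.6	14.1	417.1
Copper L-shell	2	209.2	112.5	18.6	6.5	9.5	4.6	2.8	137.7	16.8	363.8
Carbon K-shell	2	163.2	98.5	34.5	13.5	16.0	9.0	6.4	125.7	20.0	308.9
Co-60	2	402.5	166.2	6.7	0.8	6.1	0.7	0.1	173.5	6.8	583.0
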