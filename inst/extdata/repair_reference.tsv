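label	photon_energy_eV	p_correct	p_mutation	p_conversion
Titanium K-shell	4550	0.934	0.049	0.017
Aluminum K-shell	1490	0.890	0.081	0.029
Copper L-shell	960	0.863	0.099	0.037
Carbon K-shell	280	0.829	0.123	0.048
Co-60	1250000	0.963	0.0281	0.00907
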