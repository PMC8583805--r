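label	photon_energy_eV	dsb_induction	dsb_conversion	rbe_induction	rbe_conversion
Titanium K-shell	4550	10.7	9.4	1.3	1.6
Aluminum K-shell	1490	15.9	12.6	1.9	2.1
Copper L-shell	960	18.5	13.7	2.3	2.3
Carbon K-shell	280	21.2	14.7	2.6	2.4
Co-60	1250000	8.1	6.0	1.0	1.0
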