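label	photon_energy_eV	measured_dsb	measured_rbe	simulated_dsb	simulated_rbe
Titanium K-shell	4550	10.4	1.4	10.7	1.3
Aluminum K-shell	1490	14.3	1.9	15.9	1.9
Copper L-shell	960	17.4	2.3	18.5	2.3
Carbon K-shell	280	20.7	2.7	21.2	2.6
Co-60	1250000	7.6	1.0	8.1	1.0
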