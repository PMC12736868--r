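name	eps_inf	deps1	tau1	alpha1	deps2	tau2	alpha2	deps3	tau3	alpha3	deps4	tau4	alpha4	sigma_static	source
muscle	4.0	50	7.23e-12	0.10	7000	353.68e-9	0.10	1.2e6	318.31e-6	0.10	2.5e7	2.274e-3	0.00	0.20	Gabriel-type 4-Cole-Cole dispersion database, muscle (transverse)
fat_infiltrated	2.5	9	7.96e-12	0.20	35	15.92e-9	0.10	3.3e4	159.15e-6	0.05	1.0e7	15.915e-3	0.01	0.035	Gabriel-type 4-Cole-Cole dispersion database, average infiltrated fat
skin_dry	4.0	32	7.23e-12	0.00	1100	32.48e-9	0.20	0	159.15e-6	0.20	0	15.915e-3	0.20	0.0002	Gabriel-type 4-Cole-Cole dispersion database, dry skin
bladder_urine	50.0	25	8.0e-12	0.00	0	1.0e-9	0.00	0	1.0e-6	0.00	0	1.0e-3	0.00	1.75	Literature default for urine (saline-like electrolyte); not a printed ground-truth set
electrode_gel	100.0	0	1.0e-12	0.00	0	1.0e-9	0.00	0	1.0e-6	0.00	0	1.0e-3	0.00	0.30	Constant-property EKG gel fallback; user-supplied interpolation table may override
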