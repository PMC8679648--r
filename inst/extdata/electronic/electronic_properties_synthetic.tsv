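# Synthetic stand-in electronic-property table for the polarization calculus.
# The dielectric constants are the experimental liquid values quoted in the
# validation discussion; gas dipoles and refractive indices are handbook-style
# approximations (silanol gas dipoles set alcohol-like at 1.70 D), NOT the
# original curated compilation.  Replace with your own curated values for
# production use.
# Columns: compound, mu_gas (D), alpha (A^3), eps (liquid, -), n_D (-)
compound	mu_gas	alpha	eps	n_D
Met4Si	0.00	11.6	1.921	1.3587
Eth4Si	0.00	19.0	2.09	1.4240
Met3SiOH	1.70	11.4	7.17	1.3880
Eth3SiOH	1.70	18.8	2.66	1.4329
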