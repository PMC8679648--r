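quantity	value	unit
u_liq	NA	kJ/mol
u_gas	NA	kJ/mol
T	298.15	K
volume	NA	nm^3
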