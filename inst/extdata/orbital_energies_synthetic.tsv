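system	label	energy_ev
TYR295	HOMO	-9.00
TYR295	LUMO	0.76
TRP286-TYR295	HOMO	-8.00
TRP286-TYR295	LUMO	0.72
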