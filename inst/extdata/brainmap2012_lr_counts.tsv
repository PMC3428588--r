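subdomain	domain	n_left	n_right	left_fraction	z
Execution:Other	Action	3924	3270	0.55	7.7
Execution:Speech	Action	1625	1254	0.56	7.0
Imagination	Action	645	454	0.59	5.9
Inhibition	Action	1036	1254	0.45	-4.6
Language:Orthography	Cognition	1050	662	0.61	9.6
Language:Other	Cognition	660	415	0.61	7.7
Language:Phonology	Cognition	907	525	0.63	10.5
Language:Semantics	Cognition	4232	2349	0.64	24.2
Language:Speech	Cognition	3829	2523	0.60	16.7
Language:Syntax	Cognition	392	196	0.67	8.6
Memory:Explicit	Cognition	3459	2736	0.56	9.2
Memory:Working	Cognition	3591	3311	0.52	3.4
Somesthesis:Other	Perception	1157	1009	0.53	3.2
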