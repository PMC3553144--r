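position	from	to	property_change
40	Q	K	Hydrophilic/+
44	H	Q	+/Hydrophilic
49	T	A	Hydrophilic/Hydrophobic
63	C	A	Hydrophilic/Hydrophobic
64	D	Q	-/Hydrophilic
73	N	R	Hydrophilic/+
79	A	C	Hydrophobic/Hydrophilic
80	C	A	Hydrophilic/Hydrophobic
117	L	C	Hydrophobic/Hydrophilic
119	S	V	Hydrophilic/Hydrophobic
122	G	H	Hydrophilic/+
123	Y	N	Hydrophilic/Hydrophilic
128	E	K	-/+
138	N	E	Hydrophilic/-
139	A	S	Hydrophobic/Hydrophilic
143	C	K	Hydrophilic/+
154	D	Q	-/Hydrophilic
155	L	E	Hydrophobic/-
156	Q	A	Hydrophilic/Hydrophobic
170	D	F	-/Hydrophobic
172	N	D	Hydrophilic/-
174	V	K	Hydrophobic/+
175	T	A	Hydrophilic/Hydrophobic
176	Y	H	Hydrophilic/+
179	Y	N	Hydrophilic/Hydrophilic
181	P	A	Hydrophilic/Hydrophobic
183	Q	H	Hydrophilic/+
185	T	A	Hydrophilic/Hydrophobic
187	G	R	Hydrophilic/+
194	Q	V	Hydrophilic/Hydrophobic
205	L	S	Hydrophobic/Hydrophilic
208	L	N	Hydrophobic/Hydrophilic
209	P	L	Hydrophilic/Hydrophobic
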