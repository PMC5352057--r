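#patient_no	age	gender	subtype	location	extent	status	radiation	survival
1	56	M	Chondroid	Clivus	GTR	Recurrence	Y	alive
2	67	M	Chondroid	Clivus	GTR	Primary	N	alive
3	49	M	Chondroid	Clivus	STR	Primary	N	alive
4	63	F	Chondroid	Clivus	GTR	Primary	N	alive
5	62	M	Typical	Clivus	GTR	Primary	Y	alive
6	64	F	Typical	Clivus	GTR	Primary	N	alive
7	72	M	Typical	Clivus	GTR	Recurrence	N	alive
8	60	M	Chondroid	Clivus	GTR	Recurrence	Y	alive
9	58	M	unknown	Clivus	GTR	Primary	ND	alive
10	48	M	unknown	Clivus	STR	Recurrence	ND	alive
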