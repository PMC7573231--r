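protocol_id	step	agents	state
A	1		baseline
A	2	OC;M;P;G	Ln
A	3	ADP;S	OXPHOS
A	4	CytC	cytc_check
A	5	CCCP	ETS
B	1		baseline
B	2	M;P	Ln
B	3	OC;G;S;ADP	OXPHOS
B	4	CytC	cytc_check
B	5	OM	LOmy
B	6	CCCP	ETS
CI	1		baseline
CI	2	M;P;G;ADP	none
CI	3	S	OXPHOS
CI	4	CytC	cytc_check
CI	5	CCCP	ETS
CI	6	Mal	CI
CII	1		baseline
CII	2	M;P;G;ADP	none
CII	3	S	OXPHOS
CII	4	CytC	cytc_check
CII	5	CCCP	ETS
CII	6	Rot	CII
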