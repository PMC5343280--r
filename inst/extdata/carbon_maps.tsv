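reaction	substrate	sub_pos	product	prod_pos
HK	GLC	1	G6P	1
HK	GLC	2	G6P	2
HK	GLC	3	G6P	3
HK	GLC	4	G6P	4
HK	GLC	5	G6P	5
HK	GLC	6	G6P	6
PGI	G6P	1	F6P	1
PGI	G6P	2	F6P	2
PGI	G6P	3	F6P	3
PGI	G6P	4	F6P	4
PGI	G6P	5	F6P	5
PGI	G6P	6	F6P	6
PFK	F6P	1	F16BP	1
PFK	F6P	2	F16BP	2
PFK	F6P	3	F16BP	3
PFK	F6P	4	F16BP	4
PFK	F6P	5	F16BP	5
PFK	F6P	6	F16BP	6
ALD	F16BP	1	DHAP	1
ALD	F16BP	2	DHAP	2
ALD	F16BP	3	DHAP	3
ALD	F16BP	4	GA3P	1
ALD	F16BP	5	GA3P	2
ALD	F16BP	6	GA3P	3
TPI	DHAP	1	GA3P	3
TPI	DHAP	2	GA3P	2
TPI	DHAP	3	GA3P	1
GAPDH_PGM	GA3P	1	PG23	1
GAPDH_PGM	GA3P	2	PG23	2
GAPDH_PGM	GA3P	3	PG23	3
ENO	PG23	1	PEP	1
ENO	PG23	2	PEP	2
ENO	PG23	3	PEP	3
PK	PEP	1	PYR	1
PK	PEP	2	PYR	2
PK	PEP	3	PYR	3
PDH	PYR	1	CO2	1
PDH	PYR	2	ACCOA	1
PDH	PYR	3	ACCOA	2
CS	ACCOA	1	CIT	1
CS	ACCOA	2	CIT	2
CS	OAA	1	CIT	4
CS	OAA	2	CIT	3
CS	OAA	3	CIT	5
CS	OAA	4	CIT	6
ACN	CIT	1	ACO	1
ACN	CIT	2	ACO	2
ACN	CIT	3	ACO	3
ACN	CIT	4	ACO	4
ACN	CIT	5	ACO	5
ACN	CIT	6	ACO	6
IDH	ACO	1	OG2	5
IDH	ACO	2	OG2	4
IDH	ACO	3	OG2	3
IDH	ACO	4	CO2	1
IDH	ACO	5	OG2	2
IDH	ACO	6	OG2	1
OGDH	OG2	1	CO2	1
OGDH	OG2	2	SUC	1
OGDH	OG2	3	SUC	2
OGDH	OG2	4	SUC	3
OGDH	OG2	5	SUC	4
SDH	SUC	1	FUM	1
SDH	SUC	2	FUM	2
SDH	SUC	3	FUM	3
SDH	SUC	4	FUM	4
FH	FUM	1	MAL	1
FH	FUM	2	MAL	2
FH	FUM	3	MAL	3
FH	FUM	4	MAL	4
MDH	MAL	1	OAA	1
MDH	MAL	2	OAA	2
MDH	MAL	3	OAA	3
MDH	MAL	4	OAA	4
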