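id	carbon_count	symmetric
GLC	6	FALSE
G6P	6	FALSE
F6P	6	FALSE
F16BP	6	FALSE
DHAP	3	FALSE
GA3P	3	FALSE
PG23	3	FALSE
PEP	3	FALSE
PYR	3	FALSE
ACCOA	2	FALSE
CIT	6	FALSE
ACO	6	FALSE
OG2	5	FALSE
SUC	4	TRUE
FUM	4	TRUE
MAL	4	FALSE
OAA	4	FALSE
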