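#from_base	to_base	seed	mature	precursor
U	G	3	10	44
U	A	2	6	40
G	U	9	19	76
G	C	8	26	78
C	G	6	16	75
C	A	4	12	52
A	U	1	7	34
A	C	4	15	40
U	C	9	44	204
C	U	29	93	355
G	A	35	119	336
A	G	23	59	211
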