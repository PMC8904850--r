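patient	sex	S_RA	engel	outcome	n_electrodes	n_contact_points	N_SR
P1	F	5	2A	NSF	9	99	40
P2	M	5	1A	SF	12	106	30
P3	F	4	2C	NSF	13	117	47
P4	F	5	1A	SF	11	110	44
P5	M	6	1A	SF	12	124	40
P6	F	4	1A	SF	10	104	37
P7	M	3	1A	SF	12	102	38
P8	F	6	3A	NSF	15	194	60
P9	M	12	1A	SF	10	107	32
P10	M	6	1A	SF	14	193	49
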