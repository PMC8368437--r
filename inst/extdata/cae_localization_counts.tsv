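region	band	nonresponders	responders
FC	1-4	4	3
FC	4-8	4	1
FC	8-12	7	0
FC	12-30	3	2
FC	30-80	10	1
FC	80-250	3	1
MFC	1-4	3	3
MFC	4-8	4	1
MFC	8-12	7	0
MFC	12-30	3	2
MFC	30-80	5	0
MFC	80-250	3	0
LFL	1-4	1	0
LFL	4-8	0	0
LFL	8-12	0	0
LFL	12-30	0	0
LFL	30-80	5	1
LFL	80-250	0	1
TC	1-4	1	0
TC	4-8	1	0
TC	8-12	1	2
TC	12-30	0	2
TC	30-80	0	3
TC	80-250	3	6
TPJ	1-4	1	2
TPJ	4-8	0	0
TPJ	8-12	0	3
TPJ	12-30	0	1
TPJ	30-80	0	0
TPJ	80-250	0	1
POT	1-4	6	5
POT	4-8	4	2
POT	8-12	2	2
POT	12-30	3	2
POT	30-80	0	0
POT	80-250	0	0
Pc	1-4	0	3
Pc	4-8	1	0
Pc	8-12	0	1
Pc	12-30	2	3
Pc	30-80	1	1
Pc	80-250	0	0
PCC	1-4	0	2
PCC	4-8	0	0
PCC	8-12	0	0
PCC	12-30	2	0
PCC	30-80	0	1
PCC	80-250	0	0
PL	1-4	1	1
PL	4-8	2	1
PL	8-12	2	1
PL	12-30	1	0
PL	30-80	0	0
PL	80-250	0	0
MOC	1-4	2	4
MOC	4-8	0	2
MOC	8-12	1	2
MOC	12-30	1	2
MOC	30-80	0	1
MOC	80-250	0	0
TH	1-4	0	3
TH	4-8	1	4
TH	8-12	1	1
TH	12-30	3	3
TH	30-80	2	7
TH	80-250	1	1
CE	1-4	0	0
CE	4-8	1	0
CE	8-12	0	0
CE	12-30	0	0
CE	30-80	0	0
CE	80-250	1	2
DBA	1-4	0	1
DBA	4-8	0	2
DBA	8-12	0	2
DBA	12-30	1	0
DBA	30-80	3	1
DBA	80-250	4	3
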