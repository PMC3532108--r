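base	-5	-4	-3	-2	-1	T1	T2	T3	T4	+1	+2	+3	+4	+5
A	63	45	84	78	79	96	37	117	17	57	62	78	59	68
C	13	32	5	23	18	25	4	4	26	13	10	4	30	18
G	15	30	3	9	14	35	3	8	19	21	22	4	34	14
T	80	64	79	61	60	15	127	42	109	80	77	85	48	71
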