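area	layer	thickness_mm	density
FD	I	0.24	18
FD	II	0.22	92
FD	III	0.93	62
FD	IV	0.28	105
FD	V	0.55	55
FD	VI	0.68	70
FA	I	0.28	16
FA	II	0.24	68
FA	III	1.10	58
FA	IV	0.00	0
FA	V	0.95	62
FA	VI	0.90	52
OA	I	0.20	20
OA	II	0.18	100
OA	III	0.75	70
OA	IV	0.30	130
OA	V	0.45	60
OA	VI	0.55	78
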