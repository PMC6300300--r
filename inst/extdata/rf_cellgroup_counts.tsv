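model	n_cells	n_drugs	top100	top50
on_the_fly	7	29	13	10
on_the_fly	6	30	15	10
on_the_fly	5	42	16	12
on_the_fly	4	51	14	10
on_the_fly	all	152	58	42
two_level	7	29	14	12
two_level	6	30	15	14
two_level	5	42	22	20
two_level	4	51	13	8
two_level	all	152	63	54
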