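sample	species	n_l1	n_td
AG06249	macaque	449	29
AG06252	macaque	620	28
AG07098	macaque	424	26
AG07109	macaque	473	28
AG07110	macaque	635	28
AG06105	orangutan	663	52
AG06209	orangutan	803	81
GM04272	orangutan	649	62
PR00054	orangutan	775	70
PR01110	orangutan	633	47
PR00226	chimpanzee	214	4
PR00738	chimpanzee	246	7
PR00818	chimpanzee	223	4
PR01106	chimpanzee	148	3
PR01171	chimpanzee	132	5
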