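ec_pattern	sbo_label	sbo_id	category	class_label
1.-.-.-	redox reaction	200	one_to_one	oxidoreduction
1.14.-.-	hydroxylation	233	one_to_one	hydroxylation
2.-.-.-	addition of a chemical group	210	one_to_one	group transfer
2.1.1.-	methylation	214	one_to_one	methylation
2.4.-.-	glycosylation	217	one_to_one	glycosylation
2.6.1.-	transamination	402	one_to_one	transamination
2.7.-.-	phosphorylation	216	one_to_one	phosphorylation
2.8.2.-	sulfation	220	one_to_one	sulfation
3.-.-.-	hydrolysis	376	one_to_one	hydrolysis
3.5.4.-	deamination	401	one_to_one	deamination
4.-.-.-	cleavage	178	one_to_one	lyase cleavage
4.1.1.-	decarboxylation	399	one_to_one	decarboxylation
5.-.-.-	isomerisation	377	one_to_one	isomerisation
6.-.-.-	formation of a covalent bond	695	one_to_one	ligation
2.3.1.97	myristoylation	219	one_to_few	myristoylation
2.3.1.225	palmitoylation	218	one_to_few	palmitoylation
2.5.1.58	farnesylation	222	one_to_few	farnesylation
2.3.1.1	acetylation	215	one_to_many	acetylation
2.3.1.5	acetylation	215	one_to_many	acetylation
2.3.1.6	acetylation	215	one_to_many	acetylation
2.3.1.7	acetylation	215	one_to_many	acetylation
2.3.1.9	acetylation	215	one_to_many	acetylation
2.3.1.12	acetylation	215	one_to_many	acetylation
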