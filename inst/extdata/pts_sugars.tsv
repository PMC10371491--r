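substrate	phospho_product
glc__D	g6p
fru	f1p
man	man6p
acgam	acgam6p
gam	gam6p
malt	malt6p
sucr	suc6p
mnl	mnl1p
sbt__D	sbt6p
tre	tre6p
galt	galt1p
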