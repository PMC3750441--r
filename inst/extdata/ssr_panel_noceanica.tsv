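motif	total_len	context	context_name	organelle	strains
A	10	intergenic	psbB-petF	pt	IMET1,CCMP531
T	10	genic	rps12	pt	IMET1,CCMP531
T	10	intergenic	rpl16-rps3	pt	IMET1,CCMP531
A	10	intergenic	secA-rpl34	pt	IMET1,CCMP531
G	14	intergenic	psbV-clpC	pt	IMET1
TA	14	intergenic	trnK(uuu)-trnG(gcc)	pt	IMET1
T	10	intergenic	tufA-rps7	pt	CCMP531
T	11	genic	coxI	mt	IMET1,CCMP531
A	11	genic	atp1	mt	IMET1,CCMP531
A	10	intergenic	orf321	mt	IMET1,CCMP531
A	10	genic	rpl14	mt	IMET1,CCMP531
T	10	intergenic	trnD(gtc)-trnG(tcc)	mt	IMET1,CCMP531
A	10	genic	rps13	mt	IMET1,CCMP531
T	10	intergenic	trnK(ttt)-nad4L	mt	IMET1,CCMP531
A	12	genic	rps3	mt	CCMP531
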