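region	position	CCMP531	IMET1	CCMP1779	effect
rps11_mt-nad4	8512	G	A	A	NA
rps11_mt-nad4	8513	C	T	T	NA
rps11_mt-nad4	8555	-	G	G	NA
rps11_mt-nad4	8577	C	A	A	NA
nad4	8710	T	C	C	synonymous
nad4	8720	G	A	A	synonymous
nad4	8941	C	A	A	synonymous
nad4	8956	C	T	T	synonymous
rps3_mt	21403	G	C	C	synonymous
rps3_mt	21488	T	C	C	synonymous
rps3_mt	21583	A	T	T	synonymous
rps3_mt	21637	A	G	G	synonymous
rps3_mt	21682	A	G	G	synonymous
rps3_mt	21940	G	A	A	synonymous
cox2-rrn16_mt	34621	G	T	T	NA
cox2-rrn16_mt	34727	A	G	G	NA
cox2-rrn16_mt	34756	C	T	T	NA
cox2-rrn16_mt	34801	A	G	G	NA
cox2-rrn16_mt	34866	-	T	T	NA
cox2-rrn16_mt	34867	-	T	T	NA
cox2-rrn16_mt	34870	-	A	A	NA
cox2-rrn16_mt	34871	-	A	A	NA
cox2-rrn16_mt	34880	A	-	-	NA
cox2-rrn16_mt	34885	A	-	-	NA
cox2-rrn16_mt	34898	T	C	C	NA
cox2-rrn16_mt	34927	-	A	A	NA
cox2-rrn16_mt	34934	C	T	T	NA
cox2-rrn16_mt	34971	G	A	A	NA
cox2-rrn16_mt	34995	A	A	T	NA
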