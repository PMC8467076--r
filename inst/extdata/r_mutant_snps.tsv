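cluster	snp	position	ref	alt	mutants	locus_tag	orientation	product
1	C9672T	9672	C	T	R42	Mlut_00060	>	DNA gyrase subunit A
1	G10325A	10325	G	A	RE	Mlut_00060	>	DNA gyrase subunit A
2	G810889A	810889	G	A	R33	Mlut_07490	<	DNA segregation ATPase, FtsK/SpoIIIE family
2	G812767A	812767	G	A	R13	Mlut_07500	>	Flp pilus assembly protein, ATPase CpaF
2	C812940T	812940	C	T	R16	Mlut_07500	>	Flp pilus assembly protein, ATPase CpaF
2	G816694A	816694	G	A	R34	Mlut_07560	>	hypothetical protein
3	C934586T	934586	C	T	R21	Mlut_08640	>	glutamyl-tRNA synthetase
3	G935940A	935940	G	A	R16	Mlut_08660	>	tRNA-Gln
4	G1011921A	1011921	G	A	R4	Mlut_09340	<	2-oxo-acid dehydrogenase E1 component, homodimeric type
4	C1014740T	1014740	C	T	R13	Mlut_09380	>	4-azaleucine resistance probable transporter AzlC
5	G1029395A	1029395	G	A	R7	Mlut_09550	<	peptide deformylase
5	G1031740A	1031740	G	A	R13	Mlut_09580	>	translocating P-type ATPase, Cd/Co/Hg/Pb/Zn-transporting
6	G1249315A	1249315	G	A	R42	Mlut_11600	<	phosphoserine phosphatase SerB
6	C1250564T	1250564	C	T	R42	Mlut_11610	>	ABC-type molybdenum transport system
7	G1460599A	1460599	G	A	RE	Mlut_13330	>	2-oxoglutarate dehydrogenase E2 component
7	C1462336T	1462336	C	T	R4	Mlut_13350	<	protein kinase family protein
8	G1541663A	1541663	G	A	R34	Mlut_14110	>	response regulator of citrate/malate metabolism
8	C1542830T	1542830	C	T	R41	Mlut_14120	<	acyl-CoA synthetase/AMP-acid ligase
9	G1814683A	1814683	G	A	R3,R30			Intergenic sequence, Mlut_16600 promoter
10	C1962653T	1962653	C	T	R4	Mlut_18140	>	helicase family protein with metal-binding cysteine cluster
10	C1964134T	1964134	C	T	R13	Mlut_18140	>	helicase family protein with metal-binding cysteine cluster
11	C2027721T	2027721	C	T	R3,R30	Mlut_18760	>	tRNA (guanine-N(7)-)-methyltransferase
11	C2028876T	2028876	C	T	R34	Mlut_18770	<	alpha/beta hydrolase of unknown function (DUF1023)
12	G2427638A	2427638	G	A	R3,R30	Mlut_22740	<	hypothetical protein
13	G1606821A	1606821	G	A	R4	Mlut_14650	<	SAF domain-containing protein
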