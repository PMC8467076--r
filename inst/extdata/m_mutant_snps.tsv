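cluster	snp	position	ref	alt	mutants	locus_tag	orientation	product
1	G103107A	103107	G	A	M89,M106,MT	Mlut_00960	>	Cof subfamily of IIB subfamily of haloacid dehalogenase superfamily
1	G103500A	103500	G	A	M27,M2	Mlut_00970	<	Protein of unknown function DUF88
1	G106197A	106197	G	A	M33	Mlut_00990	<	Amino acid transporter
3	G341241A	341241	G	A	M43,M47,M101,M1080,M42	Mlut_03135	<	N6-DNA Methylase
3	G341448A	341448	G	A	M96	Mlut_03135	<	Hypothetical protein
4	C575082T	575082	C	T	M93			Intragenic sequence
4	G575822A	575822	G	A	M28,M28B	Mlut_05280	<	Hypothetical protein
7	C1061676T	1061676	C	T	M89,M106,MT	Mlut_09880	>	ATP-dependent Clp protease proteolytic subunit ClpP
7	C1063999T	1063999	C	T	M93	Mlut_09900	>	ATP-dependent Clp protease ATP-binding subunit ClpX
7	G1064341A	1064341	G	A	M28,M28B	Mlut_09900	>	ATP-dependent Clp protease ATP-binding subunit ClpX
13	G1606810A	1606810	G	A	M105,M27,M2	Mlut_14650	<	SAF domain-containing protein
13	G1607081A	1607081	G	A	M89,M106,MT			Intergenic sequence (Mlut_14660 promoter)
13	G1607117A	1607117	G	A	M1090			Intergenic sequence (Mlut_14660 promoter)
13	C1607204T	1607204	C	T	M96	Mlut_14660	>	DNA-binding protein, excisionase family
13	C1607261T	1607261	C	T	M9,M7,M43,M47,M101,M44,M1080,M42,M6,M3	Mlut_14660	>	DNA-binding protein, excisionase family
13	C1607314T	1607314	C	T	M93	Mlut_14660	>	DNA-binding protein, excisionase family
15	C2060795T	2060795	C	T	M93	Mlut_19080	<	Flavodoxin
15	C2061073T	2061073	C	T	M33	Mlut_19090	<	Thiol-disulfide isomerase such as thioredoxin
15	T2061826C	2061826	T	C	M43	Mlut_19090	<	Thiol-disulfide isomerase such as thioredoxin
17	C226684T	226684	C	T	M33	Mlut_02150	>	DNA-binding protein, excisionase family
18	G1878213A	1878213	G	A	M42,M1080	Mlut_17340	<	RNA polymerase sigma factor, sigma-70 family
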