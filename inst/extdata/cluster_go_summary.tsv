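cluster	category	term	count	percent
1	BP	mRNA processing	11	11.83
1	BP	mRNA metabolic process	11	11.83
1	BP	RNA splicing	9	9.68
1	CC	Ribonucleoprotein complex	19	20.43
1	CC	Macromolecular complex	34	36.56
1	CC	Intracellular organelle	60	64.52
1	CC	Organelle	60	64.52
1	CC	Intracellular part	64	68.82
1	CC	Intracellular	64	68.82
1	CC	Intracellular organelle part	35	37.63
1	CC	Organelle part	35	37.63
1	CC	Spliceosome	8	8.60
1	CC	Nucleus	38	40.86
1	CC	Intracellular membrane-bounded organelle	51	54.84
1	CC	Membrane-bounded organelle	51	54.84
1	MF	RNA binding	21	22.58
1	MF	Nucleic acid binding	31	33.33
2	BP	Sexual reproduction	18	12.41
2	BP	Gamete generation	16	11.03
2	BP	Male gamete generation	14	9.66
2	BP	Spermatogenesis	14	9.66
2	BP	Multicellular organism reproduction	16	11.03
2	BP	Reproductive process in a multicellular organism	16	11.03
2	BP	Reproductive process	18	12.41
2	BP	Reproduction	18	12.41
2	BP	Cell cycle process	14	9.66
2	CC	Intracellular organelle part	45	31.03
2	CC	Macromolecular complex	39	26.90
2	CC	Organelle part	45	31.03
2	CC	Intracellular part	90	62.09
2	CC	Intracellular membrane-bounded organelle	74	51.03
2	CC	Membrane-bounded organelle	74	51.03
2	CC	Intracellular organelle	80	55.17
2	CC	Organelle	80	55.17
3	BP	Sexual reproduction	19	9.60
3	BP	Male gamete generation	13	6.57
3	BP	Spermatogenesis	13	6.57
3	BP	Reproductive process	19	9.60
3	BP	Reproduction	19	9.60
3	BP	Gamete generation	14	7.07
3	BP	Multicellular organism reproduction	14	7.07
3	BP	Reproductive process in a multicellular organism	14	7.07
3	CC	Acrosomal vesicle	10	5.05
3	CC	Secretory granule	10	5.05
4	BP	Sexual reproduction	16	7.24
4	BP	Spermatogenesis	12	5.43
4	BP	Male gamete generation	12	5.43
4	BP	Gamete generation	13	5.88
4	BP	Reproductive process in a multicellular organism	14	6.33
4	BP	Multicellular organism reproduction	14	6.33
4	CC	Cytoplasm	73	33.03
5	BP	Oxidation reduction	28	15.56
5	BP	Lipid metabolic process	28	15.56
5	BP	Response to oxidative stress	10	5.56
5	BP	Lipid biosynthetic process	16	8.89
5	BP	Cellular ketone metabolic process	20	11.11
5	BP	Oxoacid metabolic process	19	10.56
5	BP	Carboxylic acid metabolic process	19	10.56
5	BP	Organic acid metabolic process	19	10.56
5	BP	Cellular lipid metabolic process	19	10.56
5	BP	Response to hydrogen peroxide	6	3.33
5	CC	Cytoplasm	114	63.33
5	CC	Cytoplasmic part	85	47.22
5	CC	Mitochondrion	37	20.56
5	CC	Intracellular part	128	71.11
5	CC	Intracellular	130	72.22
5	MF	Oxidoreductase activity	29	16.11
5	MF	Oxidoreductase activity, acting on CH-OH group of donors	13	7.22
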