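strain	accession	D	ani	aai	pocp	hexamer	country
Trichoderma harzianum	GCA_019097725.1	0.038	94.43	94.62	95.10	81.97	Italy
Trichoderma sp. IMV 00454	GCA_001931985.1	0.038	94.35	94.65	94.99	80.14	Hungary
Trichoderma simmonsii	GCA_019565615.1	0.039	94.38	94.65	95.18	75.93	United States
Trichoderma guizhouense	GCA_002022785.1	0.045	93.34	94.12	94.62	82.60	Austria
Trichoderma semiorbis	GCA_020045945.2	0.048	92.70	93.56	93.63	65.00	China
Trichoderma lentiforme	GCA_011066345.1	0.048	92.93	93.80	93.86	94.15	Brazil
Trichoderma atrobrunneum	GCA_003439915.1	0.049	92.43	93.36	93.30	74.53	Australia
Trichoderma harzianum	GCA_001990665.1	0.050	92.87	93.72	93.49	64.50	United States
Trichoderma harzianum CBS 226.95	GCA_003025095.1	0.051	92.86	93.59	93.43	67.66	Italy
Trichoderma harzianum	GCA_002838845.1	0.051	92.91	93.64	93.39	65.21	Australia
Trichoderma lixii	GCA_014468695.1	0.051	92.91	93.68	92.03	90.34	Brazil
Trichoderma harzianum	GCA_019393575.1	0.053	92.88	93.61	92.35	83.64	Italy
Trichoderma brevicrassum	GCA_017311225.1	0.053	92.60	93.59	94.07	95.61	Germany
Trichoderma afroharzianum	GCA_020736905.1	0.059	91.40	92.95	92.59	62.55	China
Trichoderma harzianum	GCA_000988865.1	0.060	91.49	92.93	92.32	67.72	China
Trichoderma afroharzianum	GCA_016490745.1	0.060	91.45	92.93	92.46	75.37	Brazil
Trichoderma harzianum	GCA_010015525.1	0.061	91.27	92.82	92.34	58.96	Korea
Trichoderma harzianum	GCA_002894145.1	0.084	88.09	90.25	91.20	77.24	China
Trichoderma pleuroti	GCA_001721665.1	0.088	87.56	89.05	88.25	75.93	Taiwan
Trichoderma virens FT-333	GCA_020647705.1	0.128	83.93	85.06	86.13	54.83	India
Trichoderma sp. BMH-0061	GCA_030015385.1	0.0	100	99.99	99.99	NA	Mexico
Beauveria brongniartii RCEF 3172	GCA_001636735.1	0.230	76.84	63.08	61.40	NA	China
Escovopsis weberi	GCA_003055145.1	0.263	78.61	65.97	57.39	NA	United Kingdom
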