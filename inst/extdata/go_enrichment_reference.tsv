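block	study_size	term	description	background	gene_set	expected	fisher_classic	fisher_weighted
osmotic	1879	GO:0009414	response to water deprivation	398	69	26.94	4.2e-13	2.2e-10
osmotic	1879	GO:0009611	response to wounding	222	44	15.03	9.3e-11	2.9e-10
osmotic	1879	GO:0009753	response to jasmonic acid	205	43	13.88	2.2e-11	1.8e-09
osmotic	1879	GO:0006979	response to oxidative stress	467	68	31.61	1.7e-09	2.4e-09
osmotic	1879	GO:0071456	cellular response to hypoxia	239	42	16.18	1.1e-08	1.1e-08
osmotic	1879	GO:0009737	response to abscisic acid	578	88	39.12	5.6e-13	2.6e-08
osmotic	1879	GO:0080167	response to karrikin	128	26	8.66	3.8e-07	3.8e-07
osmotic	1879	GO:0006952	defense response	1103	130	74.66	2.8e-10	2.9e-06
osmotic	1879	GO:0019761	glucosinolate biosynthetic process	52	16	3.52	1.8e-07	4.4e-06
osmotic	1879	GO:0009625	response to insect	32	11	2.17	4.5e-06	4.5e-06
osmotic	1879	GO:0009718	anthocyanin-containing compound biosynthesis	33	11	2.23	6.3e-06	1.0e-05
osmotic	1879	GO:0055114	oxidation-reduction process	754	73	51.04	0.00128	1.5e-05
osmotic	1879	GO:0009828	plant-type cell wall loosening	37	11	2.5	2.2e-05	2.2e-05
osmotic	1879	GO:0010114	response to red light	63	16	4.26	3.1e-06	2.5e-05
osmotic	1879	GO:0009651	response to salt stress	485	58	32.83	1.8e-05	5.9e-05
osmotic	1879	GO:0071215	cellular response to abscisic acid stimulus	234	36	15.84	3.2e-06	0.00018
osmotic	1879	GO:2000280	regulation of root development	97	16	6.57	0.00077	0.00041
osmotic	1879	GO:0009409	response to cold	427	50	28.9	0.00011	0.00053
osmotic	1879	GO:0019748	secondary metabolic process	363	55	24.57	1.6e-08	0.00072
osmotic	1879	GO:0010218	response to far red light	44	11	2.98	0.00013	0.00078
salt_specific	962	GO:0071456	cellular response to hypoxia	239	27	8.15	5.5e-08	5.5e-08
salt_specific	962	GO:0009733	response to auxin	337	25	11.5	0.00025	1.4e-05
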