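# Occurrence of plant taxa in the 35 upland-moa coprolites, by proxy.
# dna_k/dna_n: coprolites with a DNA detection (of the 8 with successful rbcL libraries);
# pollen_k/pollen_n: coprolites with the pollen/spore type, with min/mean/max percent of pollen sum;
# macro_kind: S seeds, L leaf, Fl florets (semicolon-separated when several kinds).
group	family	taxon	dna_k	dna_n	pollen_k	pollen_n	pollen_min	pollen_mean	pollen_max	macro_kind	macro_k	macro_n
tree_shrub	Podocarpaceae	Dacrydium cupressinum	NA	NA	29	35	0	0.5	2.5	NA	NA	NA
tree_shrub	Podocarpaceae	Prumnopitys ferruginea	NA	NA	18	35	0	0.3	1.5	NA	NA	NA
tree_shrub	Podocarpaceae	Prumnopitys taxifolia	NA	NA	26	35	0	0.6	2.6	NA	NA	NA
tree_shrub	Podocarpaceae	Podocarpus	NA	NA	17	35	0	0.2	1.2	NA	NA	NA
tree_shrub	Podocarpaceae	Halocarpus	NA	NA	2	35	0	0.02	0.3	NA	NA	NA
tree_shrub	Podocarpaceae	Phyllocladus	NA	NA	15	35	0	0.3	1.8	NA	NA	NA
tree_shrub	Fagaceae	Nothofagus menziesii	5	8	30	35	0	1.3	3.6	L	6	35
tree_shrub	Fagaceae	Fuscospora (pollen type)	NA	NA	35	35	0.3	4.8	15.2	NA	NA	NA
tree_shrub	Myrtaceae	Metrosideros	NA	NA	4	35	0	0.04	0.4	NA	NA	NA
tree_shrub	Myrtaceae	Neomyrtus	NA	NA	6	35	0	0.1	0.9	NA	NA	NA
tree_shrub	Araliaceae	Pseudopanax	1	8	4	35	0	0.1	1.4	NA	NA	NA
tree_shrub	Araliaceae	Pseudopanax colensoi	NA	NA	8	35	0	0.6	16.9	NA	NA	NA
tree_shrub	Onagraceae	Fuchsia excorticata	1	8	9	35	0	0.3	3.8	S	2	35
tree_shrub	Chloranthaceae	Ascarina lucida	NA	NA	2	35	0	0.01	0.3	NA	NA	NA
tree_shrub	Paracryphiaceae	Quintinia	1	8	NA	NA	NA	NA	NA	NA	NA	NA
tree_shrub	Elaeocarpaceae	Aristotelia	NA	NA	1	35	0	0.01	0.3	NA	NA	NA
tree_shrub	Elaeocarpaceae	Elaeocarpus/Aristotelia	7	8	NA	NA	NA	NA	NA	NA	NA	NA
tree_shrub	Grisiliniaceae	Griselinia	4	8	1	35	0	0.01	0.4	NA	NA	NA
tree_shrub	Cunoniaceae	Weinmannia	2	8	NA	NA	NA	NA	NA	NA	NA	NA
tree_shrub	Piperaceae	Macropiper	1	8	NA	NA	NA	NA	NA	NA	NA	NA
tree_shrub	Myrsinaceae	Myrsine	2	8	5	35	0	0.1	0.9	NA	NA	NA
tree_shrub	Rubiaceae	Coprosma	NA	NA	18	35	0	0.9	8.6	NA	NA	NA
tree_shrub	Rubiaceae	Coprosma cf. arborea	1	8	NA	NA	NA	NA	NA	NA	NA	NA
tree_shrub	Rubiaceae	Rubiaceae undetermined	3	8	NA	NA	NA	NA	NA	NA	NA	NA
tree_shrub	Plantaginaceae	Parahebe	NA	NA	1	35	0	0.01	0.4	NA	NA	NA
tree_shrub	Plantaginaceae	Veronica	1	8	NA	NA	NA	NA	NA	NA	NA	NA
tree_shrub	Ericaceae	Ericaceae undetermined	1	8	10	35	0	0.4	6.8	NA	NA	NA
tree_shrub	Ericaceae	Gaultheria	1	8	NA	NA	NA	NA	NA	S	10	35
tree_shrub	Ericaceae	Dracophyllum	1	8	NA	NA	NA	NA	NA	NA	NA	NA
tree_shrub	Epacridaceae	Epacridaceae undetermined	NA	NA	NA	NA	NA	NA	NA	L	1	35
tree_shrub	Coriariaceae	Coriaria	1	8	NA	NA	NA	NA	NA	NA	NA	NA
liane	Rosaceae	Rubus	NA	NA	1	35	0	0.01	0.3	NA	NA	NA
liane	Polygonaceae	Muehlenbeckia	NA	NA	1	35	0	0.02	0.7	NA	NA	NA
dicot_herb	Asteraceae	Asteraceae undetermined	1	8	33	35	0	5.9	32.5	NA	NA	NA
dicot_herb	Asteraceae	Lactuceae	NA	NA	18	35	0	0.9	6.5	NA	NA	NA
dicot_herb	Rosaceae	Acaena	2	8	19	35	0	1.5	17.3	NA	NA	NA
dicot_herb	Thymeleaceae	Pimelea	NA	NA	1	35	0	0.01	0.3	NA	NA	NA
dicot_herb	Thymeleaceae	Kelleria	NA	NA	1	35	0	0.01	0.3	NA	NA	NA
dicot_herb	Brassicaceae	Brassicaceae undetermined	1	8	26	35	0	1.5	7.5	NA	NA	NA
dicot_herb	Lobeliaceae	cf. Pratia	NA	NA	NA	NA	NA	NA	NA	S	4	35
dicot_herb	Onagraceae	Epilobium	NA	NA	14	35	0	0.1	1.0	NA	NA	NA
dicot_herb	Gentianaceae	Gentiana	NA	NA	25	35	0	3.2	14.6	NA	NA	NA
dicot_herb	Gentianaceae	Gentianaceae undetermined	1	8	NA	NA	NA	NA	NA	NA	NA	NA
dicot_herb	Droseraceae	Drosera spp.	NA	NA	5	35	0	0.1	1.4	NA	NA	NA
dicot_herb	Plantaginaceae	Plantago	NA	NA	18	35	0	0.6	2.8	NA	NA	NA
dicot_herb	Caryophyllaceae	Colobanthus	NA	NA	NA	NA	NA	NA	NA	S	2	35
dicot_herb	Caryophyllaceae	Caryophyllaceae undetermined	NA	NA	16	35	0	0.1	0.4	NA	NA	NA
dicot_herb	Oxalidaceae	Oxalis	2	8	NA	NA	NA	NA	NA	NA	NA	NA
dicot_herb	Boraginaceae	Myosotis	2	8	32	35	0	1.6	7.7	NA	NA	NA
dicot_herb	Halagoraceae	Myriophyllum	NA	NA	1	35	0	0.01	0.3	NA	NA	NA
dicot_herb	Donatiaceae	Donatia	NA	NA	2	35	0	0.02	0.3	NA	NA	NA
dicot_herb	cf. Urticaceae	cf. Urtica	NA	NA	NA	NA	NA	NA	NA	S	5	35
dicot_herb	Ranunculaceae	Ranunculus	1	8	24	35	0	0.9	4.9	S	10	35
dicot_herb	Stylidiaceae	Forstera/Phyllachne	1	8	NA	NA	NA	NA	NA	NA	NA	NA
dicot_herb	Loganiaceae	Mitrasacme	1	8	NA	NA	NA	NA	NA	NA	NA	NA
dicot_herb	Apiaceae	Apiaceae undetermined	NA	NA	20	35	0	4.2	27.4	NA	NA	NA
dicot_herb	Apiaceae	Anisotome	NA	NA	3	35	0	0.2	6.1	NA	NA	NA
dicot_herb	Violaceae	Viola	1	8	NA	NA	NA	NA	NA	NA	NA	NA
monocot	Poaceae	Poaceae (Undetermined)	1	8	35	35	0.7	36.4	86.0	S;Fl	1;3	35
monocot	Cyperaceae	Cyperaceae undetermined	2	8	27	35	0	5.7	64.7	NA	NA	NA
monocot	Cyperaceae	cf. Carex	NA	NA	NA	NA	NA	NA	NA	S	3	35
monocot	Cyperaceae	cf. Scirpus	NA	NA	NA	NA	NA	NA	NA	S	13	35
monocot	Asteliaceae	Astelia	NA	NA	20	35	0	7.2	84.1	NA	NA	NA
monocot	Xanthorrhoeaceae	Bulbinella	NA	NA	9	35	0	0.1	1.7	NA	NA	NA
monocot	Xanthorrhoeaceae	Phormium	NA	NA	14	35	0	2.9	76.7	NA	NA	NA
fern_ally	NA	Unidentified fern	NA	NA	NA	NA	NA	NA	NA	L	3	35
fern_ally	NA	Monolete fern	NA	NA	34	35	0	7.3	32.3	NA	NA	NA
fern_ally	Cyatheaceae	Cyathea colensoi	NA	NA	26	35	0	4.0	38.6	NA	NA	NA
fern_ally	Hymenophyllaceae	Hymenophyllum	NA	NA	9	35	0	0.3	3.9	NA	NA	NA
fern_ally	Ophioglossaceae	Ophioglossum	NA	NA	15	35	0	0.5	3.8	NA	NA	NA
fern_ally	Lycopodiaceae	Lycopodium australianum	NA	NA	2	35	0	0.1	1.8	NA	NA	NA
fern_ally	Lycopodiaceae	Lycopodium scariosum	NA	NA	2	35	0	0.1	2.9	NA	NA	NA
fern_ally	Anthocerotaceae	Anthoceros	NA	NA	1	35	0	0.01	0.3	NA	NA	NA
bryophyte	NA	Moss undetermined	NA	NA	NA	NA	NA	NA	NA	L	17	35
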