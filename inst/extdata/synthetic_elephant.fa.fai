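chr1	228000000	10	60	61
chr2	220961538	231800022	60	61
chr3	213923077	456444264	60	61
chr4	206884615	673932738	60	61
chr5	199846154	884265442	60	61
chr6	192807692	1087442377	60	61
chr7	185769231	1283463543	60	61
chr8	178730769	1472328939	60	61
chr9	171692308	1654038567	60	61
chr10	164653846	1828592425	60	61
chr11	157615385	1995990514	60	61
chr12	150576923	2156232834	60	61
chr13	143538462	2309319384	60	61
chr14	136500000	2455250166	60	61
chr15	129461538	2594025178	60	61
chr16	122423077	2725644420	60	61
chr17	115384615	2850107894	60	61
chr18	108346154	2967415598	60	61
chr19	101307692	3077567533	60	61
chr20	94269231	3180563699	60	61
chr21	87230769	3276404095	60	61
chr22	80192308	3365088723	60	61
chr23	73153846	3446617581	60	61
chr24	66115385	3520990670	60	61
chr25	59076923	3588207990	60	61
chr26	52038462	3648269540	60	61
chr27	45000000	3701175322	60	61
chrX	126000000	3746925334	60	61
chrM	16770	3875025346	60	61
scaffold_1	250000	3875042408	60	61
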