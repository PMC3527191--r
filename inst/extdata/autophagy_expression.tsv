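gene	orf	exp	day1	day3	day6	fc_day1	fc_day3	fc_day6
atg1	An04g03950	1.3	3.2	2.9	2.4	2.4	2.2	1.8
atg2	An08g10270	3.9	8.2	8.2	7.8	2.1	2.1	2.0
atg3	An03g04380	1.0	2.9	2.7	2.9	2.9	2.6	2.9
atg4	An11g11320	4.6	15.5	16.8	17.3	3.4	3.6	3.7
atg6	An16g07540	1.0	1.0	1.0	0.8	1.0	1.0	0.8
atg7	An02g14900	1.5	5.6	5.1	3.0	3.8	3.5	2.0
atg7	An02g14910	6.5	20.2	18.6	15.7	3.1	2.9	2.4
atg8	An07g10020	23.8	69.1	75.0	69.7	2.9	3.2	2.9
atg9	An06g01500	1.0	8.0	6.6	5.8	8.0	6.6	5.8
atg10	An18g06610	1.2	1.4	1.4	1.2	1.1	1.2	1.0
atg11	An02g07380	2.3	5.2	6.1	4.0	2.2	2.6	1.7
atg12	An11g06920	0.6	0.8	0.7	0.6	1.4	1.2	1.0
atg13	An11g04460	0.8	1.1	1.1	1.2	1.4	1.4	1.6
atg15	An03g02820	2.6	7.1	6.0	5.5	2.7	2.3	2.1
atg16	An18g02220	1.7	3.5	3.3	2.9	2.1	2.0	1.8
atg17	An02g04820	1.6	3.5	4.2	4.7	2.2	2.7	3.0
atg18	An18g03070	2.0	1.8	2.8	2.6	0.9	1.4	1.3
atg20	An02g01390	4.5	7.7	8.4	9.0	1.7	1.8	2.0
atg22	An02g14810	5.7	10.1	9.2	8.9	1.8	1.6	1.6
atg22	An09g03630	1.6	1.4	2.0	3.1	0.9	1.3	2.0
atg22	An02g03340	1.9	1.3	1.0	1.0	0.7	0.5	0.6
atg24	An01g08520	2.8	4.9	4.8	4.9	1.7	1.7	1.7
atg26	An07g06610	3.8	10.3	9.8	7.6	2.7	2.6	2.0
atg27	An01g13390	1.1	1.7	1.5	1.5	1.6	1.4	1.4
atg28	An04g03260	1.0	1.9	1.9	2.2	1.9	2.0	2.2
atg29	An02g13480	1.0	2.5	2.4	2.7	2.4	2.3	2.6
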