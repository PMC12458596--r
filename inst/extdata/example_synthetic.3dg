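chr1	0	6.60895252135	2.83491037786	0.381918982603
chr1	100000	7.44339438094	3.36794615639	0.241991709507
chr1	200000	8.04238966172	3.3304340875	1.04186513593
chr1	300000	8.01857576171	3.82592132132	1.91015385479
chr1	400000	7.04244699026	3.62998105443	1.81645202263
chr1	500000	7.27401593893	3.52647589055	0.849155530828
chr1	600000	6.39977409978	3.99937650877	0.739309220148
chr1	700000	5.57619238212	3.91989112126	1.30090981444
chr1	800000	6.54292030229	3.70031114866	1.16967809567
chr1	900000	5.62999237645	3.93853966385	0.838302513023
chr1	1000000	5.97178266693	4.46748135459	1.61509082726
chr1	1100000	5.64968008464	4.73458646897	0.706848137034
chr1	1200000	5.35667391683	4.41676084563	-0.194891436664
chr1	1300000	5.44324570897	4.91045910088	-1.06020488136
chr1	1400000	5.88279907985	4.4891440841	-1.85348067878
chr1	1500000	6.13560580948	4.01521360282	-1.00998873669
chr1	1600000	5.6270200202	4.78808677739	-0.630505468324
chr1	1700000	5.20867589621	5.6290712125	-0.287382496452
chr1	1800000	5.33015493582	6.00334569089	0.631944136341
chr1	1900000	5.36002000075	5.0082888352	0.72665386044
chr1	2000000	4.84462034154	5.26825278984	1.5432210246
chr1	2100000	5.52885845125	4.912728141	2.17994736557
chr1	2200000	5.76405509297	5.64000077545	2.82473962274
chr1	2300000	6.33114923733	4.81940906883	2.75379258289
chr1	2400000	6.8252205548	4.06384400221	2.32365892534
chr1	2500000	7.36872184903	4.78244753921	2.75749679803
chr1	2600000	6.940685717	4.25099737136	3.48848639355
chr1	2700000	7.80542926879	4.54751447601	3.08315172161
chr1	2800000	6.92689265949	4.99769338559	2.92342578296
chr1	2900000	6.78149216408	5.74025994464	3.57722514158
chr1	3000000	7.48500659091	5.17851015815	3.14190384801
chr1	3100000	6.87272216454	4.38905759128	3.18517538459
chr1	3200000	7.25235750386	5.08704575547	3.79237348388
chr1	3300000	6.79766221366	5.92485354088	3.49016443739
chr1	3400000	7.03104345131	4.99088482131	3.21954361635
chr1	3500000	7.18364319432	4.30544554675	2.50758412359
chr1	3600000	6.25041782956	4.09064587825	2.21957106664
chr1	3700000	7.14244613831	3.64094371119	2.26488615615
chr1	3800000	6.43108703868	2.94062884102	2.32427735084
chr1	3900000	5.51232016934	2.93894863644	1.92948041985
chr2	0	5.97520614974	-7.79329799581	0.795965716243
chr2	100000	6.20747488181	-7.0588777113	0.158252550471
chr2	200000	6.20750932105	-6.44391327869	0.946807396655
chr2	300000	5.53495476051	-6.51583271636	1.68335200331
chr2	400000	4.55722821181	-6.62504620971	1.5041225168
chr2	500000	3.66353445997	-7.07274330369	1.47447812515
chr2	600000	3.34058061248	-6.20393594889	1.09914548251
chr2	700000	3.01673952356	-5.68295518011	0.309394896764
chr2	800000	2.99578216778	-6.48191083473	0.910419564461
chr2	900000	2.79333309798	-6.82803302965	-0.00566656703938
chr2	1000000	2.78526306865	-7.66007020375	-0.56032773887
chr2	1100000	3.54967618545	-7.76426905203	-1.19657862247
chr2	1200000	3.77903790684	-8.27404110432	-0.367406954198
chr2	1300000	4.57433980249	-8.82519870712	-0.114978366975
chr2	1400000	4.66577916668	-7.86063074514	-0.362460668191
chr2	1500000	4.99144693652	-8.53992251846	0.295189079319
chr2	1600000	5.79086225186	-7.93919569317	0.287287498672
chr2	1700000	6.36348116465	-7.48633232905	-0.396102839389
chr2	1800000	5.39372881381	-7.36168631067	-0.605968863646
chr2	1900000	5.54866558261	-8.1553493047	-1.19426610958
chr2	2000000	5.68816252324	-7.66581235309	-0.333514010218
chr2	2100000	4.97413949208	-8.26263151083	-0.699544069001
chr2	2200000	4.13086343892	-8.7792457427	-0.847851970331
chr2	2300000	3.62342685766	-7.91876021305	-0.80232429453
chr2	2400000	3.4565775263	-6.93557541503	-0.728101969346
chr2	2500000	3.36842967156	-5.9500535896	-0.872935278062
chr2	2600000	2.44205404748	-5.67171709909	-1.12662209517
chr2	2700000	2.02910842792	-6.51702833477	-0.787616446068
chr2	2800000	1.73543453231	-5.64678533287	-1.18313226204
chr2	2900000	1.27780643971	-4.7779312465	-1.37199492502
chr2	3000000	1.87031375492	-5.5289675677	-1.66333583472
chr2	3100000	1.68193378255	-5.80240239709	-0.720072149376
chr2	3200000	1.65855589019	-5.55159806699	-1.6878276258
chr2	3300000	1.24516604858	-4.98579750066	-0.974400293841
chr2	3400000	1.69615874784	-5.48437651713	-0.234113491615
chr2	3500000	2.51830327102	-5.50597766151	0.334755362834
chr2	3600000	1.85544683479	-6.25397567304	0.368226540003
chr2	3700000	1.18087084581	-6.14702306809	1.09864311661
chr2	3800000	0.367668275517	-6.72785020974	1.13526839725
chr2	3900000	-0.362150401302	-7.00274099106	1.76120749757
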