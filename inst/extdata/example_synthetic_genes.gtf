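chr1	chromoscene	gene	197010	197010	.	.	.	gene_id "feat_00001";
chr1	chromoscene	gene	691847	691847	.	.	.	gene_id "feat_00002";
chr1	chromoscene	gene	933926	933926	.	.	.	gene_id "feat_00003";
chr1	chromoscene	gene	2070176	2070176	.	.	.	gene_id "feat_00004";
chr1	chromoscene	gene	2118035	2118035	.	.	.	gene_id "feat_00005";
chr1	chromoscene	gene	2615486	2615486	.	.	.	gene_id "feat_00006";
chr1	chromoscene	gene	3070832	3070832	.	.	.	gene_id "feat_00007";
chr1	chromoscene	gene	3024109	3024109	.	.	.	gene_id "feat_00008";
chr1	chromoscene	gene	3220944	3220944	.	.	.	gene_id "feat_00009";
chr2	chromoscene	gene	122333	122333	.	.	.	gene_id "feat_00010";
chr2	chromoscene	gene	270150	270150	.	.	.	gene_id "feat_00011";
chr2	chromoscene	gene	862756	862756	.	.	.	gene_id "feat_00012";
chr2	chromoscene	gene	1365103	1365103	.	.	.	gene_id "feat_00013";
chr2	chromoscene	gene	2037992	2037992	.	.	.	gene_id "feat_00014";
chr2	chromoscene	gene	2640385	2640385	.	.	.	gene_id "feat_00015";
chr2	chromoscene	gene	2602748	2602748	.	.	.	gene_id "feat_00016";
chr2	chromoscene	gene	3230891	3230891	.	.	.	gene_id "feat_00017";
chr2	chromoscene	gene	3309297	3309297	.	.	.	gene_id "feat_00018";
chr2	chromoscene	gene	3451359	3451359	.	.	.	gene_id "feat_00019";
chr2	chromoscene	gene	3615553	3615553	.	.	.	gene_id "feat_00020";
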