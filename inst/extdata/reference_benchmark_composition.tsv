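Dataset	Benign	Pathogenic
VariBench_DS7_train	11347	6143
VariBench_DS7_test	1377	510
MutationTaster2	1194	161
ClinVar_additions	1668	1688
UMCG_diagnostic	1176	174
UMCG_familial_cancer	301	26
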