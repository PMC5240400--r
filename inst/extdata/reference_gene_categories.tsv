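Category	Genes
CADD_PREDICTIVE	681
CADD_LESS_PREDICTIVE	732
LITTLE_DATA	774
IMPACT_PREDICTIVE	159
MAF_ONLY	178
NOT_CALIBRATED	712
ARTIFACT	1
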