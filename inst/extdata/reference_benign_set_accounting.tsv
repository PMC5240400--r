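Gene	nCandidates	removedKnown	removedAf	removedStepOver
MYH7	1799	99	246	960
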