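sample_id	subject_id	timepoint
DF01|donation1	DF01	donation1
DM01|donation1	DM01	donation1
TFP01|baseline	TFP01	baseline
TFP01|week12	TFP01	week12
TFP01|week26	TFP01	week26
TFP01|week6	TFP01	week6
TFT01|baseline	TFT01	baseline
TFT01|week12	TFT01	week12
TFT01|week26	TFT01	week26
TFT01|week6	TFT01	week6
TMP01|baseline	TMP01	baseline
TMP01|week12	TMP01	week12
TMP01|week26	TMP01	week26
TMP01|week6	TMP01	week6
TMT01|baseline	TMT01	baseline
TMT01|week12	TMT01	week12
TMT01|week26	TMT01	week26
TMT01|week6	TMT01	week6
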