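subject_id	role	arm	sex
DF01	donor	NA	female
DM01	donor	NA	male
TFT01	recipient	FMT	female
TFP01	recipient	placebo	female
TMT01	recipient	FMT	male
TMP01	recipient	placebo	male
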