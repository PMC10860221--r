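recipient_id	donor_id
TFT01	DF01
TFP01	DF01
TMT01	DM01
TMP01	DM01
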