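recipient_id	donor_id	species	timepoint
TMT01	DM01	s008	week6
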