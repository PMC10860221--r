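cluster_id	sample_id	cpm
cl|s001|01	TMT01|week6	140.54119134225607
cl|s003|01	TMT01|week6	5.31702060941807
cl|s008|01	TMT01|week6	15.98269845994563
cl|s008|02	TMT01|week6	4.421786374742496
cl|s001|01	TMT01|week12	0
cl|s003|01	TMT01|week12	15.743538357979258
cl|s008|01	TMT01|week12	37.50161118961267
cl|s008|02	TMT01|week12	12.508999634251275
cl|s001|01	TMT01|week26	15.475944001823505
cl|s003|01	TMT01|week26	4.209072324160363
cl|s008|01	TMT01|week26	17.6018682816922
cl|s008|02	TMT01|week26	10.567198709142856
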