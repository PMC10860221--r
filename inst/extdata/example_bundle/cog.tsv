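cluster_id	categories
cl|s001|01	W
cl|s001|02	O
cl|s002|01	EJ
cl|s002|02	P
cl|s003|01	RS
cl|s003|02	RS
cl|s004|01	D
cl|s004|02	U
cl|s005|01	H
cl|s005|02	S
cl|s006|01	A
cl|s006|02	R
cl|s007|01	A
cl|s007|02	G
cl|s008|01	R
cl|s008|02	B
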