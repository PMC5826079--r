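set_id	gene_name
phototrophy_rc6	pufL
phototrophy_rc6	pufM
phototrophy_rc6	pufC
phototrophy_rc6	bchX
phototrophy_rc6	bchY
phototrophy_rc6	bchZ
bch_synthesis5	bchL
bch_synthesis5	bchN
bch_synthesis5	bchB
bch_synthesis5	bchM
bch_synthesis5	bchE
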