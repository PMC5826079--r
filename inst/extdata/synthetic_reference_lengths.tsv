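marker	length
pufL	274
pufL	305
pufM	306
pufM	310
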