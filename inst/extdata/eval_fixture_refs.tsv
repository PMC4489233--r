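protein_id	method	topology
p01	annotation	iiiiiMMMMMMMMMMMMMMMooooo
p02	annotation	iiiiiMMMMMMMMMMMMMMMoooooooooooooooooooo
p03	annotation	iiiiiMMMMMMMMMMMMMMMoooooooooooooooooooo
p04	annotation	iiiiiMMMMMMMMMMMMMMMooooo
p05	annotation	iiiiiMMMMMMMMMMMMMMMooooooooooooooooooooooooo
p06	annotation	iiiiiMMMMMMMMMMMMMMMoooooMMMMMMMMMMMMMMMiiiii
p07	annotation	SSSSSSSSSSoooooMMMMMMMMMMMMMMMiiiii
p08	annotation	SSSSSSSSSSoooooooooooooooooooooooooooooo
p09	annotation	iiiiiMMMMMMMMMMMMMMMoooooooooooooooooooo
p10	annotation	iiiiiMMMMMMMMMMMMMMMooooo
p11	annotation	SSSSSSSSSSoooooooooooooooooooooooooooooooooooooooo
p12	annotation	iiiiiiiiiiiiiiiiiiiiiiiiiiiiii
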