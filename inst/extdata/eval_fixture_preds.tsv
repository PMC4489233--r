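protein_id	method	topology
p01	prediction	iiiiiMMMMMMMMMMMMMMMooooo
p02	prediction	iiiiiiiiiiiiiiiMMMMMMMMMMMMMMMoooooooooo
p03	prediction	iiiiiiiiiiiiiiiiMMMMMMMMMMMMMMMooooooooo
p04	prediction	oooooMMMMMMMMMMMMMMMiiiii
p05	prediction	iiiiiMMMMMMMMMMMMMMMoooooMMMMMMMMMMMMMMMiiiii
p06	prediction	iiiiiMMMMMMMMMMMMMMMooooooooooooooooooooooooo
p07	prediction	SSSSSSSSSSoooooMMMMMMMMMMMMMMMiiiii
p08	prediction	iMMMMMMMMMMMMMMMoooooooooooooooooooooooo
p09	prediction	SSSSSSSSSSSSSSSSSSSSoooooooooooooooooooo
p10	prediction	iiiiiiiiiiiiiiiiiiiiiiiii
p11	prediction	oooooooooooooooooooooooooooooooooooooooooooooooooo
p12	prediction	iiiiiiiiiiiiiiiiiiiiiiiiiiiiii
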