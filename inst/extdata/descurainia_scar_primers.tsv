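target_species	primer_name	seq_5to3	substituted_positions	expected_amplicon_bp	annealing_C
Descurainia sophia	DS F3	CAT GCA ACA GAA CGG CCA TCT TCT		416	63
Descurainia sophia	DS R10	GTC ATC AAG AGC TTT CGG ACA AAC A	2,3		
Lepidium densiflorum	LD F2	GTG GGC CGG TTT CCT AAC AGA CT	2	202	63
Lepidium densiflorum	LD R8	CAG CAC AGC ATT CGC GTC C	2,3		
Lepidium virginicum	LV F6	GGG CCG GTT TCC TAG AAG ACC	2,6	493	63
Lepidium virginicum	LV R11	GCA TGT CGG GTC GCT CGA A	3,9		
Erysimum cheiranthoides	EC F2	GTC CAG ATC GAG AGT AAA GTT TCG GGC	2	363	67
Erysimum cheiranthoides	EC R8	CGT CCC ATC TCA GCA ATG GAT GTG G	2,3		
Erysimum macilentum	EM F2	CAT TGT CGA TAC CTG TCC AAA ACA GAC T	2	486	63
Erysimum macilentum	EM R8	AGA CCA GTT TCC GTC CCA TCG AC	2,3		
Draba nemorosa	DN F2	CGT GGT TTC GCG TAT TGC CTT T	1	433	63
Draba nemorosa	DN R8	AGA CGT CCT CAG CTC AGA TTT ACA T	2,3		
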