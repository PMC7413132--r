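term	polarity	family
opacity	1	parenchymal
consolidation	1	parenchymal
effusion	1	pleural
pneumothorax	1	pleural
fracture	1	osseous
lesion	1	focal
hemorrhage	1	vascular
bleed	1	vascular
hematoma	1	vascular
unremarkable	-1	normal-phrase
clear	-1	normal-phrase
normal	-1	normal-phrase
stable	-1	normal-phrase
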