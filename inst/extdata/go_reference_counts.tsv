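term_label	m	k
oxygen transport	9	3
cell wall biogenesis	21	3
cellulose metabolic process	55	3
cellular cell wall organization	132	4
exocytosis	51	3
response to auxin stimulus	46	4
response to oxidative stress	186	13
chloride transport	30	2
potassium ion transport	203	5
lipid catabolic process	48	3
lipid transport	106	4
signal transduction	200	8
protein amino acid phosphorylation	1593	42
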