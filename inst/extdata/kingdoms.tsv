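# Example hierarchy configuration: child<TAB>parent, one relation per line.
# Group identifiers (leaf-label prefixes) are the leaf level of the forest.
Animalia	Opisthokonta
Fungi	Opisthokonta
Opisthokonta	Eukaryota
Plantae	Eukaryota
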