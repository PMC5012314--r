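# Phylum (class for proteobacteria) -> domain rollup used in the examples.
Bacteroidetes	Bacteria
Chlorobi	Bacteria
Actinobacteria	Bacteria
Firmicutes	Bacteria
Gammaproteobacteria	Proteobacteria
Alphaproteobacteria	Proteobacteria
Proteobacteria	Bacteria
Euryarchaeota	Archaea
Crenarchaeota	Archaea
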