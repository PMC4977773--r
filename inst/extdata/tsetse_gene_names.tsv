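gene_id	description
GMOY008502	Ferritin heavy chain-like protein
GMOY000853	Angiotensin-converting enzyme-like
GMOY000103	Lysozyme
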