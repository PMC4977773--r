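gene_id	species	ortholog_id
GMOY008502	AGAP	AGAP002465
GMOY008502	GAUT	GAUT049017
GMOY008502	GBRI	GBRI029736
GMOY008502	FBgn	FBgn0015222
GMOY008502	GFUI	GFUI020912
GMOY008502	MDOA	MDOA013394
GMOY000853	GFUI	GFUI033358
GMOY000853	GPAI	GPAI038270
GMOY000853	GPPI	GPPI044829
GMOY000103	GPAI	GPAI010329
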