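species	gene_id
AGAP	AGAP002465
GAUT	GAUT049017
GBRI	GBRI029736
FBgn	FBgn0015222
GFUI	GFUI020912
MDOA	MDOA013394
GFUI	GFUI033358
GPAI	GPAI038270
GPPI	GPPI044829
GPAI	GPAI010329
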