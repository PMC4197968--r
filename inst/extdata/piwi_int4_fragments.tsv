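construct_id	fragment_5p	fragment_3p
int4_60nt	GTAAGACTTTAAACTATATTTAAAT	CCATAAAAAATGTAATATTTAATTATTATAAACAG
int4_106nt	GTAAGACTTTAAACTATATTTAAATTAACAAGCTCTTGTGTCGCAAAC	GCAGTTTAGGGCGGTTTTATGGCCCATAAAAAATGTAATATTTAATTATTATAAACAG
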