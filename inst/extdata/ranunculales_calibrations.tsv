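label	tip_a	tip_b	min_age	max_age
root	root		125	201.5
ranunculales_crown	Euptelea_pleiosperma_A	Ranunculus_bulbosus	125	201.5
sabiaceae_crown	Sabia_japonica	Meliosma_alba	83.4
lardizabalaceae_stem	Lardizabala_biternata	Circaeaster_agrestis	110
lardizabalaceae_crown	Lardizabala_biternata	Sargentodoxa_cuneata	41.2
menispermaceae_stem	Tinospora_cordifolia	Coptis_chinensis	91
menispermaceae_crown	Tinospora_cordifolia	Menispermum_canadense	64.67
coptidoideae_ranunculoideae_crown	Coptis_chinensis	Ranunculus_bulbosus	56
euptelea_pleiosperma_tip	Euptelea_pleiosperma_A	Euptelea_pleiosperma_B		1
hypecoum_procumbens_tip	Hypecoum_procumbens_A	Hypecoum_procumbens_B		1
capnoides_sempervirens_tip	Capnoides_sempervirens_A	Capnoides_sempervirens_B		1
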