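gene_id	gene_name	elements	methylation	regulation
ENSGALG00000015433	ABCA1	exon, utr5, promoter	Hyper	Down
ENSGALG00000015960	ADAMTS2	intron	Hyper	Down
ENSGALG00000000621	ANKRD47	promoter	Hyper	Down
ENSGALG00000005974	COL6A1	promoter	Hyper	Down
ENSGALG00000003439	CRY2	exon, intron	Hyper	Down
ENSGALG00000006000	EPHB2	intron	Hypo	Down
ENSGALG00000005204	GSTT1L	promoter	Hyper	Down
ENSGALG00000011762	MALT1	promoter	Hyper	Down
ENSGALG00000017130	PLEKHM2	intron	Hyper	Up
ENSGALG00000001419	PLXNA4	intron	Hyper	Up
ENSGALG00000002699	RHOG	intron	Hyper	Down
ENSGALG00000008436	RPIA	promoter	Hyper	Up
ENSGALG00000004741	SLC44A1	intron	Hyper	Up
ENSGALG00000014525	SLC47A1	intron	Hyper	Up
ENSGALG00000015439	UBA6	exon, utr5, promoter	Hyper	Up
ENSGALG00000004583	UBE4A	intron	Hypo/hyper	Up
ENSGALG00000005475	USP5	exon, intron	Hyper	Up
ENSGALG00000002872	VAV2	intron	Hypo	Down
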