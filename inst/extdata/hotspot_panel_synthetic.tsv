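# Demonstration hotspot panel: 19 non-coding SNV hotspots in 5 genes.
# Only the TBC1D12 chr10:96162368 C>T and WDR74 chr11:62609254 G>A positions
# are real published coordinates. ALL OTHER POSITIONS ARE SYNTHETIC
# PLACEHOLDERS (plausible loci near each gene, not real hotspots) and must be
# replaced with the true panel coordinates before analysing real data.
# Coordinates are 1-based, inclusive (hg19-style notation).
gene	chrom	pos	ref	alt
ADGRG6	chr6	142706206	G	A
ADGRG6	chr6	142706209	G	A
ADGRG6	chr6	142706729	C	T
ADGRG6	chr6	142707121	C	T
ADGRG6	chr6	142707124	C	T
PLEKHS1	chr10	115511590	G	A
PLEKHS1	chr10	115511593	C	T
PLEKHS1	chr10	115511621	G	A
PLEKHS1	chr10	115511624	C	T
WDR74	chr11	62609254	G	A
WDR74	chr11	62609261	C	T
WDR74	chr11	62609264	G	T
TBC1D12	chr10	96162368	C	T
TBC1D12	chr10	96162371	C	T
TBC1D12	chr10	96162389	G	A
TBC1D12	chr10	96162392	G	A
LEPROTL1	chr8	30026458	C	T
LEPROTL1	chr8	30026461	C	A
LEPROTL1	chr8	30026490	G	A
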