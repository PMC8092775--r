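# Illustrative post-translational modification frequency table (synthetic).
# Names follow the twelve dominant modification types in curated protein
# databases; the counts are synthetic stand-ins for demonstration and are
# not asserted anywhere.
name	count
Disulfide bond	120084
Phosphoserine	85000
N-linked (GlcNAc) asparagine	60000
Phosphothreonine	40000
N6-acetyllysine	30000
Glycyl lysine isopeptide	25000
Phosphotyrosine	20000
N6-succinyllysine	15000
N6-(pyridoxal phosphate)lysine	12000
N-acetylalanine	10000
S-palmitoyl cysteine	9000
N-acetylmethionine	8000
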