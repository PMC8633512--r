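name	species	consensus
W-box	Triticum aestivum	TTGACY
W-box	Arabidopsis thaliana	TTGACY
TTGATC-motif	Triticum aestivum	TTGATC
DRE	Triticum durum	RCCGAC
I-box	Triticum aestivum	GATAAG
G-box	Arabidopsis thaliana	CACGTG
TATA-box	Triticum aestivum	TATAWAW
CAAT-box	Triticum aestivum	CCAAT
MYB-core	Hordeum vulgare	WAACCA
MYB2R	Triticum aestivum	TAACTG
ABRE	Oryza sativa	ACGTGKC
GT1-motif	Oryza sativa	GRWAAW
ARF-site	Arabidopsis thaliana	TGTCTC
GATA-motif	Triticum aestivum	GATAG
AMYBOX	Hordeum vulgare	TAACARA
P-box	Oryza sativa	TGTAAAG
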