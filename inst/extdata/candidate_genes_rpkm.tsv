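gene	target_sequence	nr_description	rpkm_a	rpkm_b	published_log2_ratio
ACT	Unigene 2464	Actin (Populus trichocarpa)	59.346	41.9122	-0.50178
CYP	Unigene 13197	Cyclophilin (Ziziphus jujuba)	40.5789	40.4744	-0.00371
EF1a	Unigene 12271	Elongation factor 1-alpha 3 (Lilium longiflorum)	685.0639	830.3061	0.27740
EIF	Unigene 19256	Eukaryotic initiation factor 4A-14 (Nicotiana tabacum)	250.9837	239.3225	-0.06918
Fbox	Unigene 7226	F-box protein family (Arabidopsis lyrata subsp. lyrata)	9.1991	8.8816	-0.05067
FLD	Unigene 28351	Flowering locus D (Arabidopsis thaliana)	3.4496	3.3721	-0.03278
GAPDH	Unigene 17625	Glyceraldehyde-3-phosphate dehydrogenase (Magnolia quinquepeta)	596.6472	656.4584	0.13783
HIS	Unigene 8208	Histone H3.2 (Arabidopsis thaliana)	153.1042	143.9564	0.28304
PP2A	Unigene 14576	Protein phosphatase 2A regulatory subunit B (Arabidopsis thaliana)	30.1756	31.5648	0.06493
RP	Unigene 15023	RNA polymerase subunit (Medicago truncatula)	75.1492	51.1261	-0.55570
SAND	Unigene 12206	SAND family protein (Arabidopsis lyrata subsp. lyrata)	29.2467	27.7054	-0.18620
TBP	Unigene 11381	TATA-box binding protein (Phaseolus vulgaris)	37.4796	41.8497	0.15911
TUB	Unigene 4780	beta-Tubulin (Eucalyptus grandis)	15.5758	15.5318	-0.00408
UBCE	Unigene 4251	Ubiquitin conjugating enzyme2-like (Solanum tuberosum)	236.2412	245.37	0.05470
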