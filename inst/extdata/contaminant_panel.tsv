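name	srna_sequence	primer_sequence	annealing_temp_C	mean_cpm_plasma	putative_origin
sRNA 1	CUAACAGACCGAGGACUUGAAU	AACAGACCGAGGACTTGAA	57	33700	algae
sRNA 2	ACGGACAAGAAUAGGCUUCGGCU	ACGGACAAGAATAGGCTTC	54	8000	fungi or plants
sRNA 3	GCCUUGGUUGUAGGAUCUGU	GCCTTGGTTGTAGGATCTGT	57	8200	plants
sRNA 4	GCCAGCAUCAGUUCGGUGUG	CAGCATCAGTTCGGTGTG	57	6800	bacteria
sRNA 5	GAGAGUAGGACGUUGCCAGGUU	AGTAGGACGTTGCCAGGTT	57	3900	bacteria
sRNA 6	UUGAAGGGUCGUUCGAGACCAGGACGUUGAUAGGCUGGGUG	GAAGGGTCGTTCGAGACC	57	3400	bacteria
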