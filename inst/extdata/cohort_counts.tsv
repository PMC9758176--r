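variant_label	alt_alleles	total_alleles	printed_freq	observed_homozygotes	patient_alleles	homozygous_alleles	compound_het_alleles	total_patient_alleles
c.620A>T	22	13686	0.00161	3	185	6	179	730
c.1807G>C	12	13686	0.00089	92	318	184	134	730
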