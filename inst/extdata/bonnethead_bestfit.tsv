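quantity	value
log_likelihood	-920.78
Ne_anc	10263
split_years_G4	1532
Ne_current_tampa	158639
Ne_current_biscayne	1026319
m_biscayne_to_tampa	0
m_tampa_to_biscayne	4.87e-4
ancestral_growth_onset_years	390000
Ne_after_ancestral_growth	51000
mu_per_base_per_generation	3.92e-9
generation_time_years	4
generation_time_years_iucn	12
sfs_total_sites	4971503
snps_retained	10358
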