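# Published local-authority summaries from the North Staffordshire chronic
# pain survey (worked-example inputs): 35+ population, LSOA counts, the
# estimated affected count (overall_n), the printed prevalence (1 dp), the
# counts of LSOAs in the region-wide lowest/highest prevalence quintile and
# the printed 20:20 value (2 dp).
la_name,population_35plus,n_lsoas,outcome,overall_n,prevalence_pct,n_lowest_quintile,n_highest_quintile,twenty_twenty_printed
Stoke-on-Trent,136718,159,chronic_pain,52699,38.5,9,56,0.30
Newcastle-under-Lyme,74399,80,chronic_pain,23103,31.1,25,4,0.26
Staffordshire Moorlands,64274,59,chronic_pain,19171,29.8,26,0,0.44
Stoke-on-Trent,136718,159,high_impact,23341,17.1,10,54,0.28
Newcastle-under-Lyme,74399,80,high_impact,8723,11.7,24,4,0.25
Staffordshire Moorlands,64274,59,high_impact,6839,10.6,26,2,0.41
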