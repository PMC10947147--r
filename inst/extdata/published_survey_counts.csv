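# Published crude respondent counts by age-sex category from the North
# Staffordshire chronic pain survey (worked-example inputs): respondents,
# number reporting each outcome, and the printed whole-percent shares.
sex,age_group,respondents,chronic_pain_n,chronic_pain_pct,high_impact_n,high_impact_pct
F,35-44,198,41,21,14,7
F,45-54,451,146,32,50,11
F,55-64,558,195,35,83,15
F,65-74,693,261,38,107,15
F,75-84,368,167,45,92,25
F,85+,90,49,54,26,29
M,35-44,103,24,23,6,6
M,45-54,313,88,28,26,8
M,55-64,437,137,31,46,11
M,65-74,555,200,36,90,16
M,75-84,325,134,41,70,22
M,85+,71,22,31,13,18
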