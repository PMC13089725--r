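schema,n_criteria,deaths,alive,total,pct_death_published
PUBLIC,0,3352,17066470,17069822,0.02
PUBLIC,1,1436,1315954,1317390,0.11
PUBLIC,2,1186,189619,190805,0.62
PUBLIC,3,806,39131,39937,2.02
PUBLIC,4,419,8028,8447,4.96
PUBLIC,5,166,1668,1834,9.05
PUBLIC,6,68,341,409,16.63
PUBLIC,7,11,68,79,13.92
PUBLIC,8,7,12,19,36.84
PUBLIC,9,4,2,6,66.67
PUBLIC,10,1,0,1,100.00
PRIVATE,0,3320,3363023,3366343,0.10
PRIVATE,1,487,183732,184219,0.26
PRIVATE,2,267,24870,25137,1.06
PRIVATE,3,136,4089,4225,3.22
PRIVATE,4,52,814,866,6.00
PRIVATE,5,14,146,160,8.75
PRIVATE,6,0,14,14,0.00
PRIVATE,7,0,1,1,0.00
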