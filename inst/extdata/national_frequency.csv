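schema,name,level,n_cases,pct_hosp_published,pct_smm_published
PUBLIC,abruptio_placentae,criterion,61056,0.32,3.81
PUBLIC,ectopic_pregnancy,criterion,130436,0.69,8.15
PUBLIC,postpartum_haemorrhage,criterion,22546,0.12,1.41
PUBLIC,ruptured_uterus,criterion,4287,0.02,0.27
PUBLIC,HAEMORRHAGIC,group,218017,1.16,13.62
PUBLIC,severe_preeclampsia,criterion,198247,1.05,12.38
PUBLIC,eclampsia,criterion,56430,0.30,3.53
PUBLIC,severe_hypertension,criterion,652396,3.47,40.75
PUBLIC,hypertensive_encephalopathy,criterion,20,0.00,0.00
PUBLIC,HYPERTENSIVE,group,865446,4.60,54.06
PUBLIC,endometritis,criterion,51966,0.28,3.25
PUBLIC,pulmonary_oedema,criterion,208,0.00,0.01
PUBLIC,respiratory_failure,criterion,10485,0.06,0.65
PUBLIC,seizures,criterion,627,0.00,0.04
PUBLIC,sepsis,criterion,4218,0.02,0.26
PUBLIC,shock,criterion,1385,0.01,0.09
PUBLIC,thyroid_crisis,criterion,12,0.00,0.00
PUBLIC,OTHER_SYSTEMIC,group,68514,0.36,4.28
PUBLIC,blood_transfusion,criterion,186101,0.99,11.63
PUBLIC,central_venous_access,criterion,2967,0.02,0.19
PUBLIC,hysterectomy,criterion,12523,0.07,0.78
PUBLIC,icu_admission,criterion,100585,0.53,6.28
PUBLIC,prolonged_stay,criterion,292625,1.56,18.28
PUBLIC,non_anaesthetic_intubation,criterion,2734,0.01,0.17
PUBLIC,surgical_intervention,criterion,131494,0.70,8.21
PUBLIC,MANAGEMENT,group,636559,3.38,39.77
PUBLIC,SMM,overall,1600796,8.51,NA
PRIVATE,abruptio_placentae,criterion,2839,0.08,1.03
PRIVATE,ectopic_pregnancy,criterion,30112,0.80,10.92
PRIVATE,postpartum_haemorrhage,criterion,1302,0.03,0.47
PRIVATE,ruptured_uterus,criterion,122,0.00,0.04
PRIVATE,HAEMORRHAGIC,group,34374,0.91,12.47
PRIVATE,severe_preeclampsia,criterion,8183,0.22,2.97
PRIVATE,eclampsia,criterion,2233,0.06,0.81
PRIVATE,severe_hypertension,criterion,50899,1.35,18.46
PRIVATE,hypertensive_encephalopathy,criterion,3,0.00,0.00
PRIVATE,HYPERTENSIVE,group,61181,1.62,22.19
PRIVATE,endometritis,criterion,2093,0.06,0.76
PRIVATE,pulmonary_oedema,criterion,23,0.00,0.01
PRIVATE,respiratory_failure,criterion,35681,0.94,12.94
PRIVATE,seizures,criterion,107,0.00,0.04
PRIVATE,sepsis,criterion,698,0.02,0.25
PRIVATE,shock,criterion,379,0.01,0.14
PRIVATE,thyroid_crisis,criterion,4,0.00,0.00
PRIVATE,OTHER_SYSTEMIC,group,38836,1.03,14.08
PRIVATE,blood_transfusion,criterion,12806,0.34,4.64
PRIVATE,central_venous_access,criterion,4482,0.12,1.63
PRIVATE,hysterectomy,criterion,10670,0.28,3.87
PRIVATE,icu_admission,criterion,95596,2.53,34.67
PRIVATE,prolonged_stay,criterion,56980,1.51,20.67
PRIVATE,non_anaesthetic_intubation,criterion,308,0.01,0.11
PRIVATE,surgical_intervention,criterion,17911,0.47,6.50
PRIVATE,MANAGEMENT,group,172780,4.57,62.66
PRIVATE,SMM,overall,275731,7.30,NA
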