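schema,name,level,deaths_with,alive_with,or_published
PUBLIC,abruptio_placentae,criterion,160,59899,6.80
PUBLIC,ectopic_pregnancy,criterion,85,128931,1.65
PUBLIC,postpartum_haemorrhage,criterion,240,21096,29.32
PUBLIC,ruptured_uterus,criterion,34,4104,20.78
PUBLIC,HAEMORRHAGIC,group,504,213774,6.24
PUBLIC,severe_preeclampsia,criterion,320,190572,4.34
PUBLIC,eclampsia,criterion,330,52443,16.40
PUBLIC,severe_hypertension,criterion,544,636331,2.22
PUBLIC,hypertensive_encephalopathy,criterion,2,14,356.88
PUBLIC,HYPERTENSIVE,group,1070,839754,3.55
PUBLIC,endometritis,criterion,162,50169,8.22
PUBLIC,pulmonary_oedema,criterion,28,160,438.70
PUBLIC,respiratory_failure,criterion,217,10110,55.18
PUBLIC,seizures,criterion,9,586,38.40
PUBLIC,sepsis,criterion,219,3819,147.52
PUBLIC,shock,criterion,269,1006,692.78
PUBLIC,thyroid_crisis,criterion,0,12,NA
PUBLIC,OTHER_SYSTEMIC,group,785,65630,33.27
PUBLIC,blood_transfusion,criterion,2181,175881,43.36
PUBLIC,central_venous_access,criterion,395,2014,517.17
PUBLIC,hysterectomy,criterion,513,10660,129.00
PUBLIC,icu_admission,criterion,2579,89783,109.15
PUBLIC,prolonged_stay,criterion,568,288306,5.24
PUBLIC,non_anaesthetic_intubation,criterion,11,2654,10.37
PUBLIC,surgical_intervention,criterion,453,127123,9.41
PUBLIC,MANAGEMENT,group,3556,614525,26.72
PUBLIC,SMM,overall,4104,1554823,13.44
PRIVATE,abruptio_placentae,criterion,15,2634,4.78
PRIVATE,ectopic_pregnancy,criterion,8,28847,0.23
PRIVATE,postpartum_haemorrhage,criterion,2,1243,1.35
PRIVATE,ruptured_uterus,criterion,2,111,15.08
PRIVATE,HAEMORRHAGIC,group,27,32834,0.69
PRIVATE,severe_preeclampsia,criterion,6,7408,0.68
PRIVATE,eclampsia,criterion,12,1967,5.11
PRIVATE,severe_hypertension,criterion,59,47539,1.04
PRIVATE,hypertensive_encephalopathy,criterion,0,3,NA
PRIVATE,HYPERTENSIVE,group,77,56792,1.14
PRIVATE,endometritis,criterion,8,1949,3.44
PRIVATE,pulmonary_oedema,criterion,0,17,NA
PRIVATE,respiratory_failure,criterion,282,30955,8.09
PRIVATE,seizures,criterion,2,92,18.19
PRIVATE,sepsis,criterion,8,602,11.13
PRIVATE,shock,criterion,20,320,52.52
PRIVATE,thyroid_crisis,criterion,0,4,0.00
PRIVATE,OTHER_SYSTEMIC,group,313,33818,8.27
PRIVATE,blood_transfusion,criterion,206,11287,15.99
PRIVATE,central_venous_access,criterion,183,3488,45.80
PRIVATE,hysterectomy,criterion,56,10037,4.72
PRIVATE,icu_admission,criterion,769,84250,9.09
PRIVATE,prolonged_stay,criterion,234,46139,4.43
PRIVATE,non_anaesthetic_intubation,criterion,1,291,2.87
PRIVATE,surgical_intervention,criterion,68,16772,3.43
PRIVATE,MANAGEMENT,group,914,150975,6.17
PRIVATE,SMM,overall,1016,246858,4.15
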