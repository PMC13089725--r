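schema,n_obstetric,n_smm,deaths_known,alive_known
PUBLIC,18807757,1600796,7456,18621293
PRIVATE,3776986,275731,4276,3576689
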