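patient_id,group,tissue,ga_birth_weeks,ga_birth_days,birth_weight_g,ga_surgery_weeks,ga_surgery_days,postnatal_age_days,sex
12244-04_B1,NEC,ileum,27,6,1438,28,4,5,male
9589-10_B,NEC,ileum,23,2,585,30,3,50,male
12106-10_C,NEC,ileum,26,2,1025,27,1,6,male
18596-11_L,NEC,colon,39,0,2360,39,4,4,male
23543-11_B,NEC,ileum,29,2,1225,29,6,4,male
6126-12_A,NEC,jejunum,26,2,912,31,0,33,male
6436-13_C,NEC,ileum,24,1,597,25,6,12,female
33-04_B,NEC,ileum,34,3,2300,35,2,6,female
13749-07_A,control,ileum,36,4,3075,39,6,23,male
3267-13,control,ileum,25,6,622,31,1,37,female
315-10_1,control,ileum,40,4,4320,41,1,4,female
873-12_5,control,ileum,25,0,870,31,5,47,female
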