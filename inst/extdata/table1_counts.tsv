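variable	level	nonsepsis	sepsis
age	65-74	5122	246
age	>=75	1783	151
sex	Male	3905	257
sex	Female	3000	140
bmi	<18.5	353	29
bmi	18.5-24	5448	306
bmi	>=24	1104	62
smoking	No	6150	346
smoking	Yes	755	51
drinking	No	6540	364
drinking	Yes	365	33
diabetes	No	4562	214
diabetes	Yes	2343	183
coronary_disease	No	6464	361
coronary_disease	Yes	441	36
cerebrovascular_disease	No	6827	363
cerebrovascular_disease	Yes	78	34
malignant_tumor	No	4399	217
malignant_tumor	Yes	2506	180
hepatic_failure	No	6842	383
hepatic_failure	Yes	63	14
pneumonia	No	6500	338
pneumonia	Yes	405	59
acute_kidney_injury	No	6783	384
acute_kidney_injury	Yes	122	13
n_comorbidities	0	2596	88
n_comorbidities	1-2	4080	272
n_comorbidities	>=3	229	37
chemotherapy	No	6871	391
chemotherapy	Yes	34	6
dialysis	No	6558	362
dialysis	Yes	347	35
rbc_infusion	No	6756	367
rbc_infusion	Yes	149	30
surgery_timing	Elective	6510	264
surgery_timing	Emergency	395	133
surgery_type	Abdominal/urogenital	3999	217
surgery_type	Cardiovascular/thoracic	548	43
surgery_type	Neurosurgery	363	82
surgery_type	Orthopedic	1042	27
surgery_type	Transplantation	64	22
surgery_type	Head and neck	889	6
surgery_duration	<=120	3084	85
surgery_duration	>120	3821	312
dexmedetomidine	No	3849	225
dexmedetomidine	Yes	3056	172
ulinastatin	No	5839	247
ulinastatin	Yes	1066	150
steroids	No	4809	202
steroids	Yes	2096	195
wbc	Normal	5803	270
wbc	Abnormal	1102	127
hct	Normal	2493	92
hct	Abnormal	4412	305
rdw	<=0.15	6075	311
rdw	>0.15	830	86
plt	Normal	6169	332
plt	Abnormal	736	65
alb	>=36	1271	164
alb	<36	5634	233
bun	<=8.2	6044	297
bun	>8.2	861	100
scr	<=116	6335	314
scr	>116	570	83
glu	<=10	6509	346
glu	>10	396	51
hscrp	<=3	166	12
hscrp	>3	6739	385
car	<0.278	6201	285
car	>=0.278	704	112
nlr	<=3.75	5188	217
nlr	>3.75	1607	180
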