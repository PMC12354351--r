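case_id	physician	department	patient_sex	birth_date	age_years	consult_date	consult_season	symptoms	syndrome	elements	element_categories	disease_name
c001	Dr_Zhao	gastroenterology	female	1962-03-14	59	2021-04-02	spring	Epigastric-pain, cracked-tongue, white-coating, stringy pulse	Deficiency of vital energy, congestion of heat and toxins.	zheng, qi, kui, xu, re, du, yong, sheng	b, b, d, d, c, c, d, d	Stomach ache
c002	Dr_Qian	gastroenterology	male	1977-08-02	44	2021-11-19	winter	Nausea, vomiting, abdominal pain, vexation, fatigue, fat tongue, yellow moss, greasy moss, fine veins	Internal obstruction by wetness	Shi, xie, nei, zu	c, c, d	Vomiting
c003	Dr_Qian	gastroenterology	male	1950-01-23	71	2021-07-08	summer	Generalized vomiting, excessive salivation, pale mouth, pale red tongue, white moss, sluggish pulse	Rebellious cold in the stomach	Wei, han, shang, ni	a, c, a, d	Vomiting
c004	Dr_Sun	hepatology	female	1985-06-30	36	2021-10-12	autumn	Weakness, Yellow urine, Stringy pulse	Stagnant heat in the liver meridian, blood stasis	gan jing, yu, re, yu	a, d, c, c	Liver accumulation
c005	Dr_Zhao	cardiology	female	1941-12-05	79	2021-05-21	spring	Tightness in chest, palpitation, shortness of breath, poor appetite, poor sleep, dry stools, dark red tongue, scanty coating	Double deficiency of the heart and spleen	xue, xin, xu, qi, pi	b, a, d, b, a	Tachycardia
c006	Dr_Li	ophthalmology	male	1968-02-17	53	2021-08-30	summer	Eye pain, itchy eyes, red tongue, thin moss, white moss, fine pulse, stringy pulse	Deficiency of liver and kidney	gan, xu, shen	a, d, a	Cataract
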