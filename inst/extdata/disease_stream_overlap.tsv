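disease	n_genetic	n_drugs	overlap	p_value
allergy	112	57	1	4.22e-01
Alzheimers disease	208	103	4	1.10e-01
arthritis	174	188	6	6.08e-02
asthma	105	80	6	7.77e-05
bipolar disorder	117	148	3	1.83e-01
cardiac arrhythmia	75	177	6	9.15e-04
chronic obstructive pulmonary disease (COPD)	154	116	6	4.18e-03
coronary heart disease	111	171	4	7.86e-02
drug dependence	75	143	6	2.96e-04
hypertension	66	188	2	2.85e-01
multiple sclerosis	71	167	4	1.83e-02
obesity	69	194	3	1.06e-01
Parkinsons disease	55	145	0	1
psoriasis	131	105	7	1.68e-04
rheumatoid arthritis	138	95	5	5.18e-03
schizophrenia	410	163	17	5.44e-05
stroke	90	156	3	1.18e-01
systemic lupus erythematosus (lupus)	126	109	5	6.30e-03
type I diabetes mellitus	87	106	3	4.39e-02
type II diabetes mellitus	130	154	4	9.14e-02
ulcerative colitis	136	51	7	1.81e-06
unipolar depression	123	121	4	3.81e-02
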