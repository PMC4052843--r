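code	display	parents
I64	Stroke, not specified as haemorrhage or infarction
I63	Cerebral infarction
I61	Intracerebral haemorrhage
I62	Other nontraumatic intracranial haemorrhage
G83	Other paralytic syndromes
G83.8	Other specified paralytic syndromes	G83
R57.2	Septic shock
D68	Other coagulation defects
I33	Acute and subacute endocarditis
I30	Acute pericarditis
I51.3	Intracardiac thrombosis
I50	Heart failure
K85	Acute pancreatitis
K72	Hepatic failure
K26	Duodenal ulcer
R31	Haematuria
S36	Injury of intra-abdominal organs
S09	Other and unspecified injuries of head
K92.2	Gastrointestinal haemorrhage, unspecified
O80	Single spontaneous delivery
Z33	Pregnant state
Z39.1	Care and examination of lactating mother
I10	Essential (primary) hypertension
R51	Headache
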