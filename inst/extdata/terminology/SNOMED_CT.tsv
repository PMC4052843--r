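code	display	parents
230690007	Cerebrovascular accident
422504002	Ischaemic stroke	230690007
274100004	Cerebral haemorrhage	230690007,1386000
1386000	Intracranial haemorrhage
50960005	Haemorrhage
12738006	Brain
66264000	Postictal paresis
21794005	Thunderclap headache
76571007	Septic shock
64779008	Blood coagulation disorder
61420007	Infectious endocarditis
3238004	Pericarditis
111293003	Ventricular thrombosis
253416000	Atrial septal aneurysm
84114007	Heart failure
75694006	Pancreatitis
235856003	Severe liver damage
45036003	Lumbar puncture
392247006	Central venous catheter insertion
86273004	Biopsy of parenchymatous organ
112746006	Operation on parenchymatous organ
283545005	Trauma with internal injuries
51868009	Duodenal ulcer
34436003	Bleeding from urinary tract
82271004	Head trauma
74474003	Gastrointestinal haemorrhage
25353009	Operation in the central nervous system
77386006	Pregnancy
169750002	Breastfeeding
386216000	Childbirth
38341003	Hypertension
29303009	Electrocardiogram
24099007	Oxygen
95460007	Posterior circulation stroke variety
472916000	Stroke of uncommon aetiology
709491003	Suspected stroke mimic
432504007	Acute ischaemic neurological deficit
281900007	No acute abnormality
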