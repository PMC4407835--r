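concept_id	preferred_term	synonyms	vocabulary
23853001	CNS disease	cns disease|central nervous system disease|cns involvement	SNOMED
91857003	acute lymphoblastic leukemia	all|acute lymphocytic leukemia|acute lymphoid leukemia	SNOMED
91861009	acute myeloid leukemia	aml|acute myelogenous leukemia|acute myeloblastic leukemia	SNOMED
93143009	leukemia	leukaemia	SNOMED
277602003	t cell acute lymphoblastic leukemia	t cell all|t all	SNOMED
277604002	precursor b cell lymphoblastic leukemia	pre b cell all|b precursor all	SNOMED
92811003	chronic myeloid leukemia	cml|chronic myelogenous leukemia	SNOMED
118600007	lymphoma	malignant lymphoma	SNOMED
118599009	hodgkin lymphoma	hodgkin disease|hodgkins lymphoma	SNOMED
46732000	non hodgkin lymphoma	nhl|non hodgkins lymphoma	SNOMED
404135006	t cell lymphoblastic lymphoma	t lbl	SNOMED
404134005	b cell lymphoblastic lymphoma	b lbl	SNOMED
109989006	multiple myeloma	plasma cell myeloma	SNOMED
126952004	neuroblastoma	nb	SNOMED
302849000	wilms tumor	nephroblastoma|wilms tumour	SNOMED
307576001	osteosarcoma	osteogenic sarcoma	SNOMED
76909002	ewing sarcoma	ewings sarcoma	SNOMED
302847003	rhabdomyosarcoma	rms	SNOMED
424413001	soft tissue sarcoma	sts	SNOMED
428061005	medulloblastoma	mb tumor	SNOMED
443333004	ependymoma	ependymal tumor	SNOMED
416901005	glioma	glial tumor	SNOMED
404087009	high grade glioma	hgg	SNOMED
404088004	low grade glioma	lgg	SNOMED
126906006	brain tumor	brain neoplasm|intracranial tumor	SNOMED
371973000	retinoblastoma	rb tumor	SNOMED
109841003	hepatoblastoma	hb tumor	SNOMED
363443007	germ cell tumor	gct	SNOMED
372064008	renal tumor	kidney tumor|renal neoplasm	SNOMED
363346000	malignant neoplasm	cancer|malignancy	SNOMED
128462008	metastatic disease	metastasis|metastases|distant spread	SNOMED
255046005	relapse	relapsed disease|disease recurrence|recurrent disease	SNOMED
765205004	refractory disease	treatment refractory	SNOMED
277022003	remission	complete remission|disease remission	SNOMED
103329007	second remission	remission 2	SNOMED
399409002	disease progression	progressive disease	SNOMED
18669006	standard risk	low risk disease	SNOMED
15508007	high risk	high risk disease	SNOMED
367336001	chemotherapy	cytotoxic chemotherapy|systemic chemotherapy	SNOMED
76334006	prior chemotherapy	previous chemotherapy|prior cytotoxic therapy	SNOMED
108290001	radiation therapy	radiotherapy|irradiation	SNOMED
765475004	prior radiation	previous radiotherapy|prior irradiation	SNOMED
234336002	stem cell transplant	hematopoietic stem cell transplantation|hsct	SNOMED
58390007	bone marrow transplant	bmt|marrow transplantation	SNOMED
86049000	immunotherapy	immune therapy	SNOMED
426406003	targeted therapy	molecular targeted therapy	SNOMED
387222003	cytarabine	ara c|cytosine arabinoside	RXNORM
387172005	vincristine	oncovin	RXNORM
372817009	doxorubicin	adriamycin	RXNORM
387374002	methotrexate	mtx	RXNORM
386906001	cyclophosphamide	cytoxan	RXNORM
387362001	asparaginase	l asparaginase	RXNORM
386902004	dexamethasone	decadron	RXNORM
373994007	prednisone	deltasone	RXNORM
387220006	imatinib	gleevec	RXNORM
421747003	corticosteroid therapy	steroid therapy|systemic steroids	RXNORM
386661006	fever	pyrexia|febrile	SNOMED
271737000	anemia	low hemoglobin|anaemia	SNOMED
302215000	thrombocytopenia	low platelet count|low platelets	SNOMED
165517008	neutropenia	low neutrophil count|low anc	SNOMED
414478003	leukocytosis	elevated white count	SNOMED
271825005	respiratory distress	breathing difficulty	SNOMED
422587007	nausea	feeling sick	SNOMED
422400008	vomiting	emesis	SNOMED
25064002	headache	cephalgia	SNOMED
22253000	pain	persistent pain	SNOMED
271807003	rash	skin eruption	SNOMED
182888003	bone pain	skeletal pain	SNOMED
30746006	lymphadenopathy	enlarged lymph nodes|swollen glands	SNOMED
16294009	splenomegaly	enlarged spleen	SNOMED
80515008	hepatomegaly	enlarged liver	SNOMED
248490000	bleeding	hemorrhage|haemorrhage	SNOMED
271598003	fatigue	tiredness|exhaustion	SNOMED
89362005	weight loss	losing weight	SNOMED
38341003	hypertension	high blood pressure|elevated blood pressure	SNOMED
73211009	diabetes mellitus	diabetes	SNOMED
195967001	asthma	bronchial asthma	SNOMED
128045006	cellulitis	skin infection	SNOMED
40733004	infection	infectious disease|active infection	SNOMED
186747009	hepatitis c	hcv infection	SNOMED
86406008	hiv infection	human immunodeficiency virus infection	SNOMED
77386006	pregnancy	pregnant	SNOMED
5935008	oral contraception	birth control pill	SNOMED
105480006	refusal of treatment	declined treatment	SNOMED
182840001	palliative care	comfort care	SNOMED
303110006	bone marrow aspirate	marrow aspiration	SNOMED
396487001	lumbar puncture	spinal tap|lp procedure	SNOMED
71388002	surgical procedure	surgery|operative procedure	SNOMED
277132007	minimal residual disease	mrd	SNOMED
413839001	chronic lung disease	chronic pulmonary disease	SNOMED
128053003	deep vein thrombosis	dvt	SNOMED
36171008	glomerulonephritis	nephritis	SNOMED
90708001	renal failure	kidney failure|renal insufficiency	SNOMED
59821001	cardiac dysfunction	reduced ejection fraction|cardiomyopathy	SNOMED
235856003	liver disease	hepatic disease|hepatic dysfunction	SNOMED
52448006	seizure disorder	epilepsy|seizures	SNOMED
271596009	failure to thrive	growth failure	SNOMED
248279007	down syndrome	trisomy 21	SNOMED
38378008	philadelphia chromosome positive	ph positive|bcr abl positive	SNOMED
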