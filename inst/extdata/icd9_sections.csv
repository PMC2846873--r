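kind,lo,hi,section
N,1,9,Intestinal infectious diseases
N,10,18,Tuberculosis
N,20,27,Zoonotic bacterial diseases
N,30,41,Other bacterial diseases
N,42,42,Human immunodeficiency virus infection
N,45,49,Poliomyelitis and other non-arthropod-borne viral diseases of central nervous system
N,50,59,Viral diseases accompanied by exanthem
N,60,66,Arthropod-borne viral diseases
N,70,79,Other diseases due to viruses and chlamydiae
N,80,88,Rickettsioses and other arthropod-borne diseases
N,90,99,Syphilis and other venereal diseases
N,100,104,Other spirochetal diseases
N,110,118,Mycoses
N,120,129,Helminthiases
N,130,136,Other infectious and parasitic diseases
N,137,139,Late effects of infectious and parasitic diseases
N,140,149,"Malignant neoplasm of lip, oral cavity, and pharynx"
N,150,159,Malignant neoplasm of digestive organs and peritoneum
N,160,165,Malignant neoplasm of respiratory and intrathoracic organs
N,170,176,"Malignant neoplasm of bone, connective tissue, skin, and breast"
N,179,189,Malignant neoplasm of genitourinary organs
N,190,199,Malignant neoplasm of other and unspecified sites
N,200,208,Malignant neoplasm of lymphatic and haematopoietic tissue
N,209,209,Neuroendocrine tumors
N,210,229,Benign neoplasms
N,230,234,Carcinoma in situ
N,235,238,Neoplasms of uncertain behavior
N,239,239,Neoplasms of unspecified nature
N,240,246,Disorders of thyroid gland
N,249,259,Diseases of other endocrine glands
N,260,269,Nutritional deficiencies
N,270,279,Other metabolic and immunity disorders
N,280,289,Diseases of the blood and blood-forming organs
N,290,294,Organic psychotic conditions
N,295,299,Other psychoses
N,300,316,"Neurotic disorders, personality disorders, and other nonpsychotic mental disorders"
N,317,319,Intellectual disabilities
N,320,327,Inflammatory diseases of the central nervous system
N,330,337,Hereditary and degenerative diseases of the central nervous system
N,338,338,Pain
N,339,339,Other headache syndromes
N,340,349,Other disorders of the central nervous system
N,350,359,Disorders of the peripheral nervous system
N,360,379,Disorders of the eye and adnexa
N,380,389,Diseases of the ear and mastoid process
N,390,392,Acute rheumatic fever
N,393,398,Chronic rheumatic heart disease
N,401,405,Hypertensive disease
N,410,414,Ischaemic heart disease
N,415,417,Diseases of pulmonary circulation
N,420,429,Other forms of heart disease
N,430,438,Cerebrovascular disease
N,440,449,"Diseases of arteries, arterioles, and capillaries"
N,451,459,Diseases of veins and lymphatics and other diseases of circulatory system
N,460,466,Acute respiratory infections
N,470,478,Other diseases of the upper respiratory tract
N,480,488,Pneumonia and influenza
N,490,496,Chronic obstructive pulmonary disease and allied conditions
N,500,508,Pneumoconioses and other lung diseases due to external agents
N,510,519,Other diseases of respiratory system
N,520,529,"Diseases of oral cavity, salivary glands, and jaws"
N,530,539,"Diseases of oesophagus, stomach, and duodenum"
N,540,543,Appendicitis
N,550,553,Hernia of abdominal cavity
N,555,558,Noninfectious enteritis and colitis
N,560,569,Other diseases of intestines and peritoneum
N,570,579,Other diseases of digestive system
N,580,589,"Nephritis, nephrotic syndrome, and nephrosis"
N,590,599,Other diseases of urinary system
N,600,608,Diseases of male genital organs
N,610,612,Disorders of breast
N,614,616,Inflammatory disease of female pelvic organs
N,617,629,Other disorders of female genital tract
N,630,639,Ectopic and molar pregnancy and other pregnancy with abortive outcome
N,640,649,"Complications mainly related to pregnancy"
N,650,659,"Normal delivery, and other indications for care in pregnancy, labour, and delivery"
N,660,669,Complications occurring mainly in the course of labour and delivery
N,670,677,Complications of the puerperium
N,678,679,Other maternal and fetal complications
N,680,686,Infections of skin and subcutaneous tissue
N,690,698,Other inflammatory conditions of skin and subcutaneous tissue
N,700,709,Other diseases of skin and subcutaneous tissue
N,710,719,Arthropathies and related disorders
N,720,724,Dorsopathies
N,725,729,"Rheumatism, excluding the back"
N,730,739,"Osteopathies, chondropathies, and acquired musculoskeletal deformities"
N,740,759,Congenital anomalies
N,760,763,Maternal causes of perinatal morbidity and mortality
N,764,779,Other conditions originating in the perinatal period
N,780,789,Symptoms
N,790,796,Nonspecific abnormal findings
N,797,799,Ill-defined and unknown causes of morbidity and mortality
N,800,804,Fracture of skull
N,805,809,Fracture of neck and trunk
N,810,819,Fracture of upper limb
N,820,829,Fracture of lower limb
N,830,839,Dislocation
N,840,848,Sprains and strains of joints and adjacent muscles
N,850,854,Intracranial injury
N,860,869,"Internal injury of thorax, abdomen, and pelvis"
N,870,879,"Open wound of head, neck, and trunk"
N,880,887,Open wound of upper limb
N,890,897,Open wound of lower limb
N,900,904,Injury to blood vessels
N,905,909,"Late effects of injuries, poisonings, toxic effects, and other external causes"
N,910,919,"Superficial injury"
N,920,924,Contusion with intact skin surface
N,925,929,Crushing injury
N,930,939,Effects of foreign body entering through orifice
N,940,949,Burns
N,950,957,Injury to nerves and spinal cord
N,958,959,Certain traumatic complications and unspecified injuries
N,960,979,"Poisoning by drugs, medicinal and biological substances"
N,980,989,Toxic effects of substances chiefly nonmedicinal as to source
N,990,995,Other and unspecified effects of external causes
N,996,999,Complications of surgical and medical care not elsewhere classified
V,1,9,Persons with potential health hazards related to communicable diseases
V,10,19,Persons with potential health hazards related to personal and family history
V,20,29,Persons encountering health services in circumstances related to reproduction and development
V,30,39,Liveborn infants according to type of birth
V,40,49,Persons with a condition influencing their health status
V,50,59,Persons encountering health services for specific procedures and aftercare
V,60,69,Persons encountering health services in other circumstances
V,70,82,Persons without reported diagnosis encountered during examination and investigation
V,83,91,Genetics and other supplementary factors
E,0,999,External causes of injury and poisoning
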