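prefix,label
I25,atherosclerotic_heart_disease
I46,cardiac_arrest
I10,hypertension
I11,hypertensive_heart_disease
I21,myocardial_infarction
I48,atrial_fibrillation
I50,heart_failure
I61,cerebral_hemorrhage
I64,unspecified_stroke
R57,cardiogenic_shock
J44,copd
J12,pneumonia
J13,pneumonia
J14,pneumonia
J15,pneumonia
J18,pneumonia
J69,pneumonitis
J84,interstitial_lung_disease
J90,pleural_effusion
J91,pleural_effusion
J96,respiratory_failure
F01,dementia
F03,dementia
G30,dementia
G20,neurodegenerative_disease
G12,neurodegenerative_disease
G81,hemiplegia
F10,alcohol_abuse
F11,drug_abuse
F19,drug_abuse
F17,nicotine_dependence
A41,other_sepsis
A40,other_sepsis
B99,other_infection
N39,urinary_tract_infection
E10,diabetes_mellitus
E11,diabetes_mellitus
E14,diabetes_mellitus
E66,obesity
E78,hyperlipidemia
D64,anemia
L89,pressure_ulcer
M80,osteoporosis
M81,osteoporosis
N17,kidney_failure
N19,kidney_failure
N18,chronic_kidney_disease
C50,breast_cancer
C61,prostate_cancer
C34,lung_cancer
C85,non_hodgkin_lymphoma
C78,secondary_malignancy
C79,secondary_malignancy
C15,gastrointestinal_cancer
C16,gastrointestinal_cancer
C18,gastrointestinal_cancer
C25,gastrointestinal_cancer
C,other_cancer
K70,liver_disease
K74,liver_disease
K92,gastrointestinal_disease
K56,gastrointestinal_disease
T39,poisoning
T50,poisoning
X4,poisoning
T14,open_wound
S06,traumatic_brain_injury
S0,open_wound
S72,fracture
T71,suffocation
W,other_physical_harm
Y,other_physical_harm
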