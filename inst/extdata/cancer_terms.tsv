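oncotree_code	label	ncit_code
ACC	Adrenocortical Carcinoma	C9325
ALL	Acute Lymphoid Leukemia	C3167
AML	Acute Myeloid Leukemia	C3171
ATC	Anaplastic Thyroid Cancer	C3878
BCC	Basal Cell Carcinoma	C2921
BLCA	Bladder Urothelial Carcinoma	C39851
CCRCC	Renal Clear Cell Carcinoma	C4033
CESC	Cervical Squamous Cell Carcinoma	C27676
CHOL	Cholangiocarcinoma	C4436
CLL	Chronic Lymphocytic Leukemia	C3163
CML	Chronic Myelogenous Leukemia	C3174
COAD	Colon Adenocarcinoma	C4349
COADREAD	Colorectal Adenocarcinoma	C5105
CSCC	Cutaneous Squamous Cell Carcinoma	C4819
DIPG	Diffuse Intrinsic Pontine Glioma	C114967
DLBCL	Diffuse Large B-Cell Lymphoma	C8851
ES	Ewing Sarcoma	C4817
ESCC	Esophageal Squamous Cell Carcinoma	C4025
FL	Follicular Lymphoma	C3209
GBM	Glioblastoma Multiforme	C3058
GIST	Gastrointestinal Stromal Tumor	C3868
HCC	Hepatocellular Carcinoma	C3099
HGSOC	High-Grade Serous Ovarian Cancer	C105555
HL	Hodgkin Lymphoma	C9357
HNSC	Head and Neck Squamous Cell Carcinoma	C34447
IDC	Breast Invasive Ductal Carcinoma	C4017
ILC	Breast Invasive Lobular Carcinoma	C4018
LMS	Leiomyosarcoma	C3157
LUAD	Lung Adenocarcinoma	C3512
LUSC	Lung Squamous Cell Carcinoma	C3493
MBL	Medulloblastoma	C3222
MCC	Merkel Cell Carcinoma	C9231
MCL	Mantle Cell Lymphoma	C4337
MDS	Myelodysplastic Syndromes	C3247
MEL	Melanoma	C3224
MESO	Pleural Mesothelioma	C7376
MPN	Myeloproliferative Neoplasms	C4345
MTC	Medullary Thyroid Cancer	C3879
NBL	Neuroblastoma	C3270
NSCLC	Non-Small Cell Lung Cancer	C2926
OS	Osteosarcoma	C9145
PAAD	Pancreatic Adenocarcinoma	C8294
PCM	Plasma Cell Myeloma	C3242
PRAD	Prostate Adenocarcinoma	C2919
PRCC	Papillary Renal Cell Carcinoma	C6975
PTC	Papillary Thyroid Cancer	C4035
READ	Rectal Adenocarcinoma	C9382
RGNT	Rosette-Forming Glioneuronal Tumor	C40360
RMS	Rhabdomyosarcoma	C3359
SCLC	Small Cell Lung Cancer	C4917
STAD	Stomach Adenocarcinoma	C4004
SYNS	Synovial Sarcoma	C3400
UEC	Uterine Endometrioid Carcinoma	C6287
UM	Uveal Melanoma	C7712
WT	Wilms Tumor	C3267
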