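gene	category	therapeutic_target
APC	HIGH_PENETRANT	FALSE
BAP1	HIGH_PENETRANT	FALSE
BRCA1	HIGH_PENETRANT	TRUE
BRCA2	HIGH_PENETRANT	TRUE
DICER1	HIGH_PENETRANT	FALSE
FH	HIGH_PENETRANT	FALSE
HOXB13	HIGH_PENETRANT	FALSE
MLH1	HIGH_PENETRANT	TRUE
MSH2	HIGH_PENETRANT	TRUE
PALB2	HIGH_PENETRANT	TRUE
PMS2	HIGH_PENETRANT	TRUE
POT1	HIGH_PENETRANT	FALSE
RB1	HIGH_PENETRANT	FALSE
ATM	MODERATE_PENETRANT	TRUE
BARD1	MODERATE_PENETRANT	FALSE
BRIP1	MODERATE_PENETRANT	TRUE
CHEK2	MODERATE_PENETRANT	FALSE
MITF	MODERATE_PENETRANT	FALSE
MRE11A	MODERATE_PENETRANT	FALSE
MUTYH	MODERATE_PENETRANT	FALSE
NF1	MODERATE_PENETRANT	FALSE
RAD50	MODERATE_PENETRANT	FALSE
RAD51C	MODERATE_PENETRANT	FALSE
SMARCB1	MODERATE_PENETRANT	FALSE
BLM	AR_CANCER_RISK	FALSE
CASP8	AR_CANCER_RISK	FALSE
ERCC1	AR_CANCER_RISK	FALSE
ERCC2	AR_CANCER_RISK	FALSE
ERCC3	AR_CANCER_RISK	FALSE
ERCC4	AR_CANCER_RISK	FALSE
FANCA	AR_CANCER_RISK	FALSE
FANCC	AR_CANCER_RISK	FALSE
FANCG	AR_CANCER_RISK	FALSE
FANCM	AR_CANCER_RISK	FALSE
HAX1	AR_CANCER_RISK	FALSE
MPL	AR_CANCER_RISK	FALSE
NBN	AR_CANCER_RISK	FALSE
SBDS	AR_CANCER_RISK	FALSE
XPC	AR_CANCER_RISK	FALSE
PARK2	AR_NONCANCER	FALSE
WRN	AR_NONCANCER	FALSE
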