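name	system	threshold	direction	threshold_male	threshold_female	anchors
sbp	cardiovascular	140	greater	NA	NA	Hypertension
dbp	cardiovascular	90	greater	NA	NA	Hypertension
bmi	metabolic	30	greater	NA	NA	Obesity; Morbid obesity; Grade I, II or III obesity
triglycerides	metabolic	150	greater_equal	NA	NA	Hypertriglyceridemia
cholesterol	metabolic	200	greater_equal	NA	NA	Hypercholesterolemia
crp	inflammation	10	greater_equal	NA	NA	Sepsis; Infection; Auto-Immune inflammatory syndrome
hba1c	inflammation	6.5	greater_equal	NA	NA	Diabetes; Impaired glycemic control
albumin	inflammation	3.5	greater_equal	NA	NA
creatinine_clearance	inflammation	NA	less	110	100	Renal failure; Insufficiency; Acute kidney injury; Chronic renal failure
homocysteine	inflammation	50	greater	NA	NA	Hyperhomocysteinemia; Vitamin deficiency
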