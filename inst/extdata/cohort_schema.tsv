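column	type	description
id	integer	subject identifier
age	numeric	age at surgery, years
sex	character	male / female
drinking	integer	ever alcohol drinking (0/1)
family_history	integer	family cancer history (0/1)
bmi	numeric	body-mass index, kg/m^2
fbg	numeric	fasting blood glucose, mmol/L
glucose_2h	numeric	2-h plasma glucose, mmol/L (may be NA)
diabetes_dx	integer	previously diagnosed diabetes (0/1)
sbp	numeric	systolic blood pressure, mm Hg
dbp	numeric	diastolic blood pressure, mm Hg
antihypertensive	integer	on antihypertensive therapy (0/1)
triglycerides	numeric	serum triglycerides, mmol/L
hdlc	numeric	HDL cholesterol, mmol/L
neutrophil	numeric	neutrophil count, 10^9/L
lymphocyte	numeric	lymphocyte count, 10^9/L
monocyte	numeric	monocyte count, 10^9/L
eosinophil	numeric	eosinophil count, 10^9/L
basophil	numeric	basophil count, 10^9/L
wbc	numeric	white blood cell count, 10^9/L
rbc	numeric	red blood cell count, 10^12/L
hemoglobin	numeric	hemoglobin, g/L
rdw	numeric	red cell distribution width, %
platelet	numeric	platelet count, 10^9/L
tnm_stage	character	TNM stage: I/II or III/IV
invasion_depth	character	invasion depth: T1/T2 or T3/T4
n_category	character	regional nodes: N0, N1, N2, N3
distant_metastasis	integer	distant metastasis (0/1)
lauren	character	Lauren type: intestinal / diffuse
embolus	integer	tumor embolus (0/1)
tumor_size	numeric	tumor size, cm
positive_nodes	integer	number of positive regional nodes
smoking	integer	ever cigarette smoking (0/1)
time_months	numeric	follow-up time, months
event	integer	1 = cancer-specific death, 0 = censored
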