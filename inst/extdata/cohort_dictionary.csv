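column,units,coding
id,-,integer participant identifier
age,years,integer 30-74
sex,-,male / female
height,cm,positive real
weight,kg,positive real (bmi * (height/100)^2)
bmi,kg/m2,positive real >= 18.5
waist,cm,positive real
hip,cm,positive real
sbp,mm Hg,positive real
dbp,mm Hg,positive real
fpg,mmol/L,fasting plasma glucose
tc,mmol/L,total cholesterol
hdl,mmol/L,HDL cholesterol
ldl,mmol/L,LDL cholesterol
tg,mmol/L,triglycerides
uric_acid,umol/L,serum uric acid
insulin,uIU/mL,fasting insulin
creatinine,mg/dL,serum creatinine
hscrp,mg/L,high-sensitivity C-reactive protein
hba1c,%,hemoglobin A1c
smoker,-,0 / 1
drinker,-,0 / 1
on_antihypertensive,-,0 / 1
on_lipid_lowering,-,0 / 1
on_diabetes_treatment,-,0 / 1
gen_phenotype,-,generator-assigned MHNW/MHOW/MHO/MUNW/MUOW/MUO
gen_metabolic_health,-,generator-assigned MH / MU
gen_bmi_category,-,generator-assigned normal / overweight / obese
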