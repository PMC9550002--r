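# Default variable specification for the elderly surgical sepsis cohort.
# Cutpoint "sides": left  => boundary belongs to the lower group (<=c vs >c)
#                   right => boundary belongs to the upper group (<c vs >=c)
sepsis:
  role: outcome
  vtype: categorical
  levels: ["0", "1"]
  reference: "0"
# --- confounders: demographics (model 1) ---
age:
  role: confounder
  vtype: continuous
  cutpoints: [75]
  sides: [right]
  levels: ["65-74", ">=75"]
  reference: "65-74"
  min: 65
sex:
  role: confounder
  vtype: categorical
  levels: [Male, Female]
  reference: Male
bmi:
  role: confounder
  vtype: continuous
  cutpoints: [18.5, 24]
  sides: [right, right]
  levels: ["<18.5", "18.5-24", ">=24"]
  reference: "18.5-24"
  min: 0
smoking:
  role: confounder
  vtype: categorical
  levels: ["No", "Yes"]
  reference: "No"
drinking:
  role: confounder
  vtype: categorical
  levels: ["No", "Yes"]
  reference: "No"
# --- confounders: preoperative comorbidities (added in model 2) ---
diabetes:
  role: confounder
  vtype: categorical
  levels: ["No", "Yes"]
  reference: "No"
coronary_disease:
  role: confounder
  vtype: categorical
  levels: ["No", "Yes"]
  reference: "No"
cerebrovascular_disease:
  role: confounder
  vtype: categorical
  levels: ["No", "Yes"]
  reference: "No"
malignant_tumor:
  role: confounder
  vtype: categorical
  levels: ["No", "Yes"]
  reference: "No"
hepatic_failure:
  role: confounder
  vtype: categorical
  levels: ["No", "Yes"]
  reference: "No"
pneumonia:
  role: confounder
  vtype: categorical
  levels: ["No", "Yes"]
  reference: "No"
acute_kidney_injury:
  role: confounder
  vtype: categorical
  levels: ["No", "Yes"]
  reference: "No"
n_comorbidities:
  role: confounder
  vtype: categorical
  levels: ["0", "1-2", ">=3"]
  reference: "0"
# --- confounders: preoperative management (added in model 3) ---
chemotherapy:
  role: confounder
  vtype: categorical
  levels: ["No", "Yes"]
  reference: "No"
dialysis:
  role: confounder
  vtype: categorical
  levels: ["No", "Yes"]
  reference: "No"
rbc_infusion:
  role: confounder
  vtype: categorical
  levels: ["No", "Yes"]
  reference: "No"
# --- putative risk factors: intraoperative ---
surgery_timing:
  role: putative_risk
  vtype: categorical
  levels: [Elective, Emergency]
  reference: Elective
surgery_type:
  role: putative_risk
  vtype: categorical
  levels: [Abdominal/urogenital, Cardiovascular/thoracic, Neurosurgery,
           Orthopedic, Transplantation, Head and neck]
  reference: Abdominal/urogenital
surgery_duration:
  role: putative_risk
  vtype: continuous
  cutpoints: [120]
  sides: [left]
  levels: ["<=120", ">120"]
  reference: "<=120"
  min: 0
dexmedetomidine:
  role: putative_risk
  vtype: categorical
  levels: ["No", "Yes"]
  reference: "No"
ulinastatin:
  role: putative_risk
  vtype: categorical
  levels: ["No", "Yes"]
  reference: "No"
steroids:
  role: putative_risk
  vtype: categorical
  levels: ["No", "Yes"]
  reference: "No"
# --- putative risk factors: preoperative laboratory variables ---
wbc:
  role: putative_risk
  vtype: categorical
  levels: [Normal, Abnormal]
  reference: Normal
hct:
  role: putative_risk
  vtype: categorical
  levels: [Normal, Abnormal]
  reference: Normal
rdw:
  role: putative_risk
  vtype: continuous
  cutpoints: [0.15]
  sides: [left]
  levels: ["<=0.15", ">0.15"]
  reference: "<=0.15"
  min: 0
plt:
  role: putative_risk
  vtype: categorical
  levels: [Normal, Abnormal]
  reference: Normal
alb:
  role: putative_risk
  vtype: continuous
  cutpoints: [36]
  sides: [right]
  levels: ["<36", ">=36"]
  reference: ">=36"
  min: 0
bun:
  role: putative_risk
  vtype: continuous
  cutpoints: [8.2]
  sides: [left]
  levels: ["<=8.2", ">8.2"]
  reference: "<=8.2"
  min: 0
scr:
  role: putative_risk
  vtype: continuous
  cutpoints: [116]
  sides: [left]
  levels: ["<=116", ">116"]
  reference: "<=116"
  min: 0
glu:
  role: putative_risk
  vtype: continuous
  cutpoints: [10]
  sides: [left]
  levels: ["<=10", ">10"]
  reference: "<=10"
  min: 0
hscrp:
  role: putative_risk
  vtype: continuous
  cutpoints: [3]
  sides: [left]
  levels: ["<=3", ">3"]
  reference: "<=3"
  min: 0
car:
  role: putative_risk
  vtype: continuous
  cutpoints: [0.278]
  sides: [right]
  levels: ["<0.278", ">=0.278"]
  reference: "<0.278"
  min: 0
nlr:
  role: putative_risk
  vtype: continuous
  cutpoints: [3.75]
  sides: [left]
  levels: ["<=3.75", ">3.75"]
  reference: "<=3.75"
  min: 0
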