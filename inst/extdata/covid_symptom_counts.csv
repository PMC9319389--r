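#name: covid_symptom_counts
#source_kind: symptoms
#total_patients: 112
variable,group,count
Low-grade fever (37.3-38.0),fever,46
Moderate-grade fever (38.1-39.0),fever,31
High-grade fever (>39.0),fever,7
Dizziness,,2
Palpitation,,2
Nausea and vomiting,,4
Throat pain,,4
Headache,,8
Abdominal pain and diarrhea,,14
Expectoration,,15
Dyspnea,,18
Myalgia,,18
Chest distress,,24
Fatigue,,38
Dry Cough,,48
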