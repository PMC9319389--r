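#name: covid_symptom_weights
#source_kind: symptoms
#total_patients: 112
variable,group,weight_pct
Dizziness,,0.7
Palpitation,,0.7
Throat pain,,1.4
Nausea and vomiting,,1.4
High-grade fever (>39.0),fever,2.5
Headache,,2.9
Abdominal pain and diarrhea,,5
Expectoration,,5.4
Dyspnea,,6.5
Myalgia,,6.5
Chest distress,,8.6
Moderate-grade fever (38.1-39.0),fever,11.1
Fatigue,,13.6
Low-grade fever (37.3-38.0),fever,16.5
Dry Cough,,17.2
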