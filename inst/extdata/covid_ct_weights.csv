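#name: covid_ct_weights
#source_kind: image_features
#total_patients: 112
variable,group,weight_pct
No lesion,distribution of pulmonary lesions,3.2
Peripheral,distribution of pulmonary lesions,13.1
Central,distribution of pulmonary lesions,0.3
Diffuse,distribution of pulmonary lesions,5.2
No involvement,involvement of the lung,3.2
Single lobe,involvement of the lung,5
Unilateral multilobe,involvement of the lung,0.4
Bilateral multilobe,involvement of the lung,13.5
GGO,,18.5
Crazy-paving pattern,,10
Consolidation,,9.4
Linear opacities,,7.3
Air bronchogram,,6.3
Cavitation,,0
Bronchiectasis,,4.4
Pleural effusion,,2.8
Pericardial effusion,,0.3
Lymphadenopathy,,0
Pneumothorax,,0.3
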