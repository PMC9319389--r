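#name: covid_ct_bounds
#source_kind: image_features
#total_patients: 112
# Published prevalence-weight bounds per CT variable, from two CT reading
# sessions; each pair is stored as (lower, higher) since the source columns
# are not consistently ordered.
variable,group,weight_min_pct,weight_max_pct
No lesion,distribution of pulmonary lesions,1.7,21.2
Peripheral,distribution of pulmonary lesions,52.4,63.8
Central,distribution of pulmonary lesions,0,2.1
Diffuse,distribution of pulmonary lesions,12.7,44.1
No involvement,involvement of the lung,1.7,21.2
Single lobe,involvement of the lung,1.5,34.0
Unilateral multilobe,involvement of the lung,0,2.9
Bilateral multilobe,involvement of the lung,42.5,95.6
GGO,,76.5,98.1
Crazy-paving pattern,,36.1,62.7
Consolidation,,25.5,75.0
Linear opacities,,6.3,83.1
Air bronchogram,,17.0,50.0
Cavitation,,0,0
Bronchiectasis,,6.3,45.2
Pleural effusion,,4.2,27.9
Pericardial effusion,,0,4.4
Lymphadenopathy,,0,0
Pneumothorax,,0,3.8
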