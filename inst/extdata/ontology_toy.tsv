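child	parent
depressive_disorder	mood_disorder
mood_disorder	mental_disorder
major_depressive_disorder	depressive_disorder
depressive_disorder_nec	depressive_disorder
dysthymic_disorder	depressive_disorder
postpartum_depression	major_depressive_disorder
recurrent_major_depression	major_depressive_disorder
single_episode_major_depression	major_depressive_disorder
psychotic_depression	major_depressive_disorder
melancholia	major_depressive_disorder
treatment_resistant_depression	recurrent_major_depression
seasonal_affective_disorder	depressive_disorder_nec
atypical_depression	depressive_disorder_nec
screening_for_depression	depressive_disorder_nec
minor_depression	depressive_disorder_nec
depression_adverse_event	adverse_event
adverse_event	clinical_finding
depressed_mood	mood_symptom
mood_symptom	clinical_finding
anxiety_disorder	mental_disorder
generalized_anxiety_disorder	anxiety_disorder
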