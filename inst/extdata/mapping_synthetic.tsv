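code	atom	asserted_status	is_anaphylaxis_diagnosis_term
Sudden onset of signs and symptoms	sudden_onset	present	FALSE
Rapid progression of signs and symptoms	rapid_progression	present	FALSE
Urticaria, generalized	generalized_urticaria	present	FALSE
Erythema, generalized	generalized_erythema	present	FALSE
Angioedema	angioedema	present	FALSE
Pruritus, generalized	generalized_pruritus	present	FALSE
Skin rash	skin_rash	present	FALSE
Prickle sensation, generalized	generalized_prickle_sensation	present	FALSE
Urticaria at injection site	localized_injection_site_urticaria	present	FALSE
Eyes red and itchy	red_itchy_eyes	present	FALSE
Generalized pruritus with skin rash	generalized_pruritus	present	FALSE
Generalized pruritus with skin rash	skin_rash	present	FALSE
Generalized pruritus without skin rash	generalized_pruritus	present	FALSE
Generalized pruritus without skin rash	skin_rash	absent	FALSE
Hypotension, measured	measured_hypotension	present	FALSE
Tachycardia	tachycardia	present	FALSE
Capillary refill time > 3 sec	capillary_refill_gt3s	present	FALSE
Capillary refill time > 3 sec without hypotension	capillary_refill_gt3s	present	FALSE
Capillary refill time > 3 sec without hypotension	measured_hypotension	absent	FALSE
Central pulse volume, reduced	reduced_central_pulse_volume	present	FALSE
Consciousness, decreased or loss of	decreased_consciousness	present	FALSE
Wheeze, bilateral	bilateral_wheeze	present	FALSE
Stridor	stridor	present	FALSE
Upper airway swelling	upper_airway_swelling	present	FALSE
Tachypnoea	tachypnoea	present	FALSE
Accessory respiratory muscle use	accessory_muscle_use	present	FALSE
Chest wall recession	chest_wall_recession	present	FALSE
Cyanosis	cyanosis	present	FALSE
Grunting	grunting	present	FALSE
Cough, persistent dry	persistent_dry_cough	present	FALSE
Hoarse voice	hoarse_voice	present	FALSE
Difficulty breathing	difficulty_breathing	present	FALSE
Difficulty breathing without wheeze or stridor	difficulty_breathing	present	FALSE
Difficulty breathing without wheeze or stridor	bilateral_wheeze	absent	FALSE
Difficulty breathing without wheeze or stridor	stridor	absent	FALSE
Sensation of throat closure	sensation_of_throat_closure	present	FALSE
Sneezing and rhinorrhea	sneezing_rhinorrhea	present	FALSE
Diarrhoea	diarrhea	present	FALSE
Abdominal pain	abdominal_pain	present	FALSE
Nausea	nausea	present	FALSE
Vomiting	vomiting	present	FALSE
Mast cell tryptase, elevated	elevated_mast_cell_tryptase	present	FALSE
Anaphylaxis		present	TRUE
Anaphylactic reaction		present	TRUE
Anaphylactic shock		present	TRUE
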