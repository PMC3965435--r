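# Brighton anaphylaxis criteria catalog -- original encoding.
# Minor criteria that distinguish themselves from a major criterion by the
# absence of another finding keep that negation explicitly (e.g. generalized
# pruritus WITHOUT skin rash), so under an open-world reading they evaluate
# to unknown whenever the negated finding is unreported. Pairing this catalog
# with closed-world completion recovers the intended behaviour.
variant: original
atoms:
  - sudden_onset
  - rapid_progression
  - generalized_urticaria
  - generalized_erythema
  - angioedema
  - generalized_pruritus
  - skin_rash
  - generalized_prickle_sensation
  - localized_injection_site_urticaria
  - red_itchy_eyes
  - measured_hypotension
  - tachycardia
  - capillary_refill_gt3s
  - reduced_central_pulse_volume
  - decreased_consciousness
  - bilateral_wheeze
  - stridor
  - upper_airway_swelling
  - tachypnoea
  - accessory_muscle_use
  - chest_wall_recession
  - cyanosis
  - grunting
  - persistent_dry_cough
  - hoarse_voice
  - difficulty_breathing
  - sensation_of_throat_closure
  - sneezing_rhinorrhea
  - diarrhea
  - abdominal_pain
  - nausea
  - vomiting
  - elevated_mast_cell_tryptase
temporal_atoms: [sudden_onset, rapid_progression]
criteria:
  - id: derm_major_urticaria_or_erythema
    system: dermatologic_mucosal
    weight: major
    expr: [or, [atom, generalized_urticaria], [atom, generalized_erythema]]
  - id: derm_major_angioedema
    system: dermatologic_mucosal
    weight: major
    expr: [atom, angioedema]
  - id: derm_major_pruritus_with_rash
    system: dermatologic_mucosal
    weight: major
    expr: [and, [atom, generalized_pruritus], [atom, skin_rash]]
  - id: derm_minor_pruritus_without_rash
    system: dermatologic_mucosal
    weight: minor
    expr: [and, [atom, generalized_pruritus], [not, [atom, skin_rash]]]
  - id: derm_minor_prickle_sensation
    system: dermatologic_mucosal
    weight: minor
    expr: [atom, generalized_prickle_sensation]
  - id: derm_minor_injection_site_urticaria
    system: dermatologic_mucosal
    weight: minor
    expr: [atom, localized_injection_site_urticaria]
  - id: derm_minor_red_itchy_eyes
    system: dermatologic_mucosal
    weight: minor
    expr: [atom, red_itchy_eyes]
  - id: cardio_major_measured_hypotension
    system: cardiovascular
    weight: major
    expr: [atom, measured_hypotension]
  - id: cardio_major_uncompensated_shock
    system: cardiovascular
    weight: major
    expr: [at_least, 3,
           [atom, tachycardia],
           [atom, capillary_refill_gt3s],
           [atom, reduced_central_pulse_volume],
           [atom, decreased_consciousness]]
  - id: cardio_minor_reduced_peripheral_circulation
    system: cardiovascular
    weight: minor
    expr: [at_least, 2,
           [atom, tachycardia],
           [and, [atom, capillary_refill_gt3s], [not, [atom, measured_hypotension]]],
           [atom, reduced_central_pulse_volume],
           [atom, decreased_consciousness]]
  - id: resp_major_bilateral_wheeze
    system: respiratory
    weight: major
    expr: [atom, bilateral_wheeze]
  - id: resp_major_stridor
    system: respiratory
    weight: major
    expr: [atom, stridor]
  - id: resp_major_upper_airway_swelling
    system: respiratory
    weight: major
    expr: [atom, upper_airway_swelling]
  - id: resp_major_respiratory_distress
    system: respiratory
    weight: major
    expr: [at_least, 2,
           [atom, tachypnoea],
           [atom, accessory_muscle_use],
           [atom, chest_wall_recession],
           [atom, cyanosis],
           [atom, grunting]]
  - id: resp_minor_persistent_dry_cough
    system: respiratory
    weight: minor
    expr: [atom, persistent_dry_cough]
  - id: resp_minor_hoarse_voice
    system: respiratory
    weight: minor
    expr: [atom, hoarse_voice]
  - id: resp_minor_difficulty_breathing_no_wheeze_stridor
    system: respiratory
    weight: minor
    expr: [and,
           [atom, difficulty_breathing],
           [not, [atom, bilateral_wheeze]],
           [not, [atom, stridor]]]
  - id: resp_minor_throat_closure_sensation
    system: respiratory
    weight: minor
    expr: [atom, sensation_of_throat_closure]
  - id: resp_minor_sneezing_rhinorrhea
    system: respiratory
    weight: minor
    expr: [atom, sneezing_rhinorrhea]
  - id: gi_minor_diarrhea
    system: gastrointestinal
    weight: minor
    expr: [atom, diarrhea]
  - id: gi_minor_abdominal_pain
    system: gastrointestinal
    weight: minor
    expr: [atom, abdominal_pain]
  - id: gi_minor_nausea
    system: gastrointestinal
    weight: minor
    expr: [atom, nausea]
  - id: gi_minor_vomiting
    system: gastrointestinal
    weight: minor
    expr: [atom, vomiting]
  - id: lab_minor_elevated_mast_cell_tryptase
    system: laboratory
    weight: minor
    expr: [atom, elevated_mast_cell_tryptase]
level_rules:
  level_1:
    [and,
     [ge_major, dermatologic_mucosal, 1],
     [or, [ge_major, cardiovascular, 1], [ge_major, respiratory, 1]]]
  level_2:
    [or,
     [and, [ge_major, cardiovascular, 1], [ge_major, respiratory, 1]],
     [and, [ge_major, cardiovascular, 1], [minor_systems_excluding, [cardiovascular], 1]],
     [and, [ge_major, respiratory, 1], [minor_systems_excluding, [respiratory], 1]],
     [and,
      [ge_major, dermatologic_mucosal, 1],
      [or, [ge_minor, cardiovascular, 1], [ge_minor, respiratory, 1]]]]
  # "2 different systems" read as excluding both cardiovascular and
  # respiratory (the reading implemented by the ABC tool).
  level_3:
    [and,
     [or, [ge_minor, cardiovascular, 1], [ge_minor, respiratory, 1]],
     [minor_systems_excluding, [cardiovascular, respiratory], 2]]
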