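risks:
- name: diet_low_in_fruits
  direction: harmful_low
  exposure_unit: g/day
  mediator: none
  category: food
- name: diet_low_in_vegetables
  direction: harmful_low
  exposure_unit: g/day
  mediator: none
  category: food
- name: diet_low_in_whole_grains
  direction: harmful_low
  exposure_unit: g/day
  mediator: none
  category: food
- name: diet_low_in_nuts_and_seeds
  direction: harmful_low
  exposure_unit: g/day
  mediator: none
  category: food
- name: diet_low_in_milk
  direction: harmful_low
  exposure_unit: g/day
  mediator: none
  category: food
- name: diet_high_in_red_meat
  direction: harmful_high
  exposure_unit: g/day
  mediator: none
  category: food
- name: diet_high_in_processed_meat
  direction: harmful_high
  exposure_unit: g/day
  mediator: none
  category: food
- name: diet_high_in_sugar_sweetened_beverages
  direction: harmful_high
  exposure_unit: g/day
  mediator: bmi
  category: food
- name: diet_low_in_fibre
  direction: harmful_low
  exposure_unit: g/day
  mediator: none
  category: fibre
- name: diet_low_in_calcium
  direction: harmful_low
  exposure_unit: g/day
  mediator: none
  category: nutrient
- name: diet_low_in_seafood_omega3
  direction: harmful_low
  exposure_unit: g/day
  mediator: none
  category: nutrient
- name: diet_low_in_polyunsaturated_fatty_acids
  direction: harmful_low
  exposure_unit: '% of daily energy'
  mediator: none
  category: nutrient
- name: diet_high_in_trans_fatty_acids
  direction: harmful_high
  exposure_unit: '% of daily energy'
  mediator: none
  category: nutrient
- name: diet_high_in_sodium
  direction: harmful_high
  exposure_unit: g/day urinary sodium equivalent
  mediator: sbp
  category: nutrient
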