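scenario:
  name: covid19_vision2030
  description: pandemic shock window 2020-2021 / Vision-2030 policy goals from 2022
  parameters: []
  overlays:
    covid_gdp_gap:
      kind: step
      t0: 2020.0
      t1: 2022.0
      level: 1.0
    covid_excess_mort:
      kind: step
      t0: 2020.0
      t1: 2022.0
      level: 0.0008
    ghg_lockdown:
      kind: step
      t0: 2020.0
      t1: 2021.0
      level: 0.21654399999999999
    covid_food_stress:
      kind: step
      t0: 2020.0
      t1: 2022.0
      level: 0.5
    vision_active:
      kind: step
      t0: 2022.0
      t1: 2051.0
      level: 1.0
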