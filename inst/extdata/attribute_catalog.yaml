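attributes:
- name: orr
  label: Likelihood of responding to treatment (ORR)
  kind: benefit
  levels:
  - '25'
  - '40'
  - '55'
  - '70'
  - '85'
  reference_index: 1
  direction: 1
  numeric_values:
  - 25.0
  - 40.0
  - 55.0
  - 70.0
  - 85.0
- name: dor
  label: Length of time in response (DOR)
  kind: benefit
  levels:
  - 3mo
  - 6mo
  - 9mo
  - 12mo
  - 15mo
  reference_index: 1
  direction: 1
  numeric_values:
  - 3.0
  - 6.0
  - 9.0
  - 12.0
  - 15.0
- name: os
  label: Lifespan (OS)
  kind: benefit
  levels:
  - 6mo
  - 12mo
  - 18mo
  - 24mo
  reference_index: 1
  direction: 1
  numeric_values:
  - 6.0
  - 12.0
  - 18.0
  - 24.0
- name: neuropathy
  label: Tingling or pain in hands/feet (peripheral neuropathy)
  kind: risk
  levels:
  - '0'
  - '25'
  - '50'
  reference_index: 1
  direction: -1
  numeric_values:
  - 0.0
  - 25.0
  - 50.0
- name: ocular
  label: Temporary vision change
  kind: risk
  levels:
  - '0'
  - '20'
  - '40'
  - '60'
  reference_index: 1
  direction: -1
  numeric_values:
  - 0.0
  - 20.0
  - 40.0
  - 60.0
- name: crs
  label: Inflammatory response (CRS)
  kind: risk
  levels:
  - none
  - high
  reference_index: 1
  direction: -1
- name: diarrhea
  label: Severe diarrhea
  kind: risk
  levels:
  - '0'
  - '10'
  - '20'
  reference_index: 1
  direction: -1
  numeric_values:
  - 0.0
  - 10.0
  - 20.0
- name: admin
  label: Administration
  kind: administration
  levels:
  - ivsc_twice_weekly
  - ivsc_q3w
  - ivsc_weekly_pills
  - ivsc_monthly_pills
  - cart_once
  reference_index: 2
  direction: 0
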