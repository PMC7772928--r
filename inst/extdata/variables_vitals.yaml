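# Routine vital-sign dictionary (mortality-style tasks).
# Units: heart_rate bpm; resp_rate breaths/min; temperature degC;
# pressures mmHg; spo2 %; glucose mg/dL.
- variable_id: heart_rate
  kind: real
  v_min: 20
  v_max: 220
  normal_low: 60
  normal_high: 100
  display_name: Heart rate
- variable_id: resp_rate
  kind: real
  v_min: 4
  v_max: 60
  normal_low: 12
  normal_high: 20
  display_name: Respiratory rate
- variable_id: temperature
  kind: real
  v_min: 32
  v_max: 42.5
  normal_low: 36
  normal_high: 38
  display_name: Temperature
- variable_id: sysbp
  kind: real
  v_min: 50
  v_max: 250
  normal_low: 90
  normal_high: 140
  display_name: SysBP
- variable_id: diasbp
  kind: real
  v_min: 30
  v_max: 150
  normal_low: 60
  normal_high: 90
  display_name: DiasBP
- variable_id: meanbp
  kind: real
  v_min: 40
  v_max: 180
  normal_low: 70
  normal_high: 105
  display_name: MeanBP
- variable_id: spo2
  kind: real
  v_min: 50
  v_max: 100
  normal_low: 94
  normal_high: 100
  display_name: SPO2
- variable_id: glucose
  kind: real
  v_min: 30
  v_max: 500
  normal_low: 70
  normal_high: 140
  display_name: Glucose
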