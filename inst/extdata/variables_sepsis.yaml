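# Vital signs plus the laboratory variables referenced by the SIRS
# (sepsis-2) criteria. Units: wbc 10^3 cells/uL; paco2 mmHg; band %.
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
- variable_id: wbc
  kind: real
  v_min: 0.1
  v_max: 100
  normal_low: 4
  normal_high: 12
  display_name: WBC
- variable_id: paco2
  kind: real
  v_min: 10
  v_max: 130
  normal_low: 35
  normal_high: 45
  display_name: PaCO2
- variable_id: band
  kind: real
  v_min: 0
  v_max: 50
  normal_low: 0
  normal_high: 10
  display_name: Band neutrophils
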