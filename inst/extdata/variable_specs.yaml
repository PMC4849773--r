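- variable: TMP
  units: degC
  plausibility_low: 30.0
  plausibility_high: 43.0
  normal_low: 36.5
  normal_high: 38.5
  microdialysis: no
- variable: RR
  units: cycles/min
  plausibility_low: 0.0
  plausibility_high: 60.0
  normal_low: 10.0
  normal_high: 18.0
  microdialysis: no
- variable: MV
  units: L/min
  plausibility_low: 0.0
  plausibility_high: 30.0
  normal_low: 5.0
  normal_high: 8.0
  microdialysis: no
- variable: CO2EX
  units: mmHg
  plausibility_low: 5.0
  plausibility_high: 150.0
  normal_low: 35.0
  normal_high: 45.0
  microdialysis: no
- variable: SPO2
  units: '%'
  plausibility_low: 0.0
  plausibility_high: 100.0
  normal_low: 89.0
  microdialysis: no
- variable: HR
  units: beats/min
  plausibility_low: 20.0
  plausibility_high: 250.0
  normal_low: 60.0
  normal_high: 80.0
  microdialysis: no
- variable: MAP
  units: mmHg
  plausibility_low: 20.0
  plausibility_high: 250.0
  normal_low: 70.0
  normal_high: 110.0
  microdialysis: no
- variable: CVP
  units: mmHg
  plausibility_low: -5.0
  plausibility_high: 50.0
  normal_low: 2.0
  normal_high: 6.0
  microdialysis: no
- variable: CI
  units: L/min/m2
  plausibility_low: 0.5
  plausibility_high: 15.0
  normal_low: 2.4
  normal_high: 4.0
  microdialysis: no
- variable: SVV
  units: '%'
  plausibility_low: 0.0
  plausibility_high: 50.0
  normal_high: 12.0
  microdialysis: no
- variable: ELWI
  units: ml/kg
  plausibility_low: 0.0
  plausibility_high: 30.0
  normal_low: 3.0
  normal_high: 7.0
  microdialysis: no
- variable: GEDI
  units: ml/m2
  plausibility_low: 200.0
  plausibility_high: 2000.0
  normal_low: 680.0
  normal_high: 800.0
  microdialysis: no
- variable: ICP
  units: mmHg
  plausibility_low: 0.0
  plausibility_high: 150.0
  normal_high: 20.0
  microdialysis: no
- variable: CPP
  units: mmHg
  plausibility_low: 0.0
  plausibility_high: 200.0
  normal_low: 60.0
  normal_high: 90.0
  microdialysis: no
- variable: pbtO2
  units: mmHg
  plausibility_low: 0.0
  plausibility_high: 150.0
  normal_low: 15.0
  microdialysis: no
- variable: rCBF
  units: ml/100g/min
  plausibility_low: 0.0
  plausibility_high: 200.0
  normal_low: 35.0
  microdialysis: no
- variable: TW%
  units: '%'
  plausibility_low: 0.0
  plausibility_high: 100.0
  microdialysis: no
- variable: BrT
  units: degC
  plausibility_low: 30.0
  plausibility_high: 43.0
  normal_low: 36.5
  normal_high: 37.5
  microdialysis: no
- variable: SjVo2
  units: '%'
  plausibility_low: 0.0
  plausibility_high: 100.0
  normal_low: 50.0
  normal_high: 75.0
  microdialysis: no
- variable: lactate
  units: mmol/L
  plausibility_low: 0.0
  plausibility_high: 20.0
  normal_low: 2.7
  normal_high: 3.3
  microdialysis: yes
- variable: pyruvate
  units: umol/L
  plausibility_low: 0.0
  plausibility_high: 1000.0
  microdialysis: yes
- variable: glucose
  units: mmol/L
  plausibility_low: 0.0
  plausibility_high: 20.0
  normal_low: 1.9
  normal_high: 2.3
  microdialysis: yes
- variable: LPR
  units: ratio
  plausibility_low: 0.0
  plausibility_high: 200.0
  normal_high: 40.0
  microdialysis: yes
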