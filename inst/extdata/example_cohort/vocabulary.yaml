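longitudinal:
- name: bnp
  kind: continuous
- name: carboxyhemoglobin
  kind: continuous
- name: corneal_reflex
  kind: binary
- name: fio2
  kind: continuous
- name: gag_reflex
  kind: binary
- name: gcs
  kind: ordinal
- name: hemoglobin
  kind: continuous
- name: lactate
  kind: continuous
- name: map
  kind: continuous
- name: methemoglobin
  kind: continuous
- name: o2_hemoglobin
  kind: continuous
- name: pco2
  kind: continuous
- name: peep
  kind: continuous
- name: ph
  kind: continuous
- name: po2
  kind: continuous
- name: pulse
  kind: continuous
- name: respirations
  kind: continuous
- name: spo2
  kind: continuous
- name: troponin_i
  kind: continuous
- name: troponin_t
  kind: continuous
- name: dopamine
  kind: continuous
- name: epinephrine
  kind: continuous
- name: levothyroxine
  kind: continuous
- name: lidocaine
  kind: continuous
- name: norepinephrine
  kind: continuous
static:
- name: age
  kind: continuous
- name: bmi
  kind: continuous
- name: dialysis
  kind: binary
- name: sex
  kind: binary
- name: weight
  kind: continuous
encodings:
  sex:
    male: 0.0
    female: 1.0
  dialysis:
    'no': 0.0
    'yes': 1.0
  corneal_reflex:
    absent: 0.0
    present: 1.0
  gag_reflex:
    absent: 0.0
    present: 1.0
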