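- name: darch_arch_cross_section
  pose:
  - 1.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 1.0
  - 0.0
  - -30.0
  - 0.0
  - 0.0
  - 1.0
  - 11.5
  - 0.0
  - 0.0
  - 0.0
  - 1.0
  required:
  - Arch
  - RArch
- name: darch_ring_coronal
  pose:
  - 1.0
  - 0.0
  - -0.0
  - 0.0
  - 0.0
  - 0.0
  - 1.0
  - 4.8
  - 0.0
  - -1.0
  - 0.0
  - 30.0
  - 0.0
  - 0.0
  - 0.0
  - 1.0
  required:
  - Arch
  - RArch
  - DAO
- name: hrh_four_chamber
  pose:
  - 1.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 1.0
  - 0.0
  - -30.0
  - 0.0
  - 0.0
  - 1.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 1.0
  required:
  - LA
  - RA
  - LV
  - RV
- name: hrh_vsd
  pose:
  - 1.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 1.0
  - 0.0
  - -30.0
  - 0.0
  - 0.0
  - 1.0
  - -2.0
  - 0.0
  - 0.0
  - 0.0
  - 1.0
  required:
  - LV
  - RV
  - VSD
- name: hrh_pa_origin
  pose:
  - -0.211592943181149
  - 0.193073060999571
  - 0.958097708750102
  - -8.458858496653786
  - -2.695949407563224e-19
  - 9.802936344565835e-01
  - -1.975459193299179e-01
  - -3.134214236703084e+01
  - -9.773578804081641e-01
  - -4.179932248444315e-02
  - -2.074232152964139e-01
  - 5.753979674533294e+00
  - 0.0e+00
  - 0.0e+00
  - 0.0e+00
  - 1.0e+00
  required:
  - PA
  - RV
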