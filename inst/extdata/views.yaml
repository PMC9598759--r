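- name: four_chamber
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
- name: lvot
  pose:
  - 0.447213595499958
  - 0.596284793999944
  - 0.666666666666667
  - -14.555210486664985
  - 0.0
  - 0.74535599249993
  - -0.666666666666667
  - -23.360679774997898
  - -0.894427190999916
  - 0.298142396999972
  - 0.333333333333333
  - -5.610938576665825
  - 0.0
  - 0.0
  - 0.0
  - 1.0
  required:
  - LV
  - AO
- name: rvot
  pose:
  - 0.832050294337844
  - -0.514916610921561
  - -0.206284249251759
  - 12.447498327646825
  - 4.455883885260051e-17
  - 3.718842189989051e-01
  - -9.282791216329142e-01
  - -1.382319323663382e+01
  - 5.547001962252291e-01
  - 7.723749163823411e-01
  - 3.094263738776382e-01
  - -2.017124749147023e+01
  - 0.0e+00
  - 0.0e+00
  - 0.0e+00
  - 1.0e+00
  required:
  - RV
  - PA
- name: three_vessel
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
  - 8.0
  - 0.0
  - 0.0
  - 0.0
  - 1.0
  required:
  - PA
  - AO
  - SVC
- name: three_vessel_trachea
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
  - 9.5
  - 0.0
  - 0.0
  - 0.0
  - 1.0
  required:
  - AO
  - DA
  - SVC
  - Trachea
- name: aortic_arch
  pose:
  - -0.021614544297861
  - -0.440193124493607
  - -0.897642927128238
  - 14.972460401474883
  - -3.361441039960816e-19
  - 8.978526848660489e-01
  - -4.402959871255104e-01
  - -2.403558054598147e+01
  - 9.997663784478832e-01
  - -9.516797117894774e-03
  - -1.940667662999064e-02
  - 4.05217058020351e+00
  - 0.0e+00
  - 0.0e+00
  - 0.0e+00
  - 1.0e+00
  required:
  - AO
  - Arch
  - DAO
- name: ductal
  pose:
  - 0.064766729929625
  - 0.31696586351786
  - -0.946222971639666
  - -10.675642572202474
  - 3.289777518888126e-18
  - 9.482138117245695e-01
  - 3.176327553240736e-01
  - -2.634641435173709e+01
  - 9.97900431252649e-01
  - -2.0572034880877e-02
  - 6.141270785950566e-02
  - 3.950494379759643e+00
  - 0.0e+00
  - 0.0e+00
  - 0.0e+00
  - 1.0e+00
  required:
  - PA
  - DA
  - DAO
- name: bicaval
  pose:
  - -0.447213595499958
  - -0.87287156094397
  - -0.195180014589707
  - 22.352813494985757
  - 1.321532933794107e-17
  - 2.182178902359929e-01
  - -9.759000729485331e-01
  - -1.046536707079786e+00
  - 8.944271909999161e-01
  - -4.364357804719843e-01
  - -9.759000729485343e-02
  - 1.37597400808262e+01
  - 0.0e+00
  - 0.0e+00
  - 0.0e+00
  - 1.0e+00
  required:
  - SVC
  - IVC
  - RA
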