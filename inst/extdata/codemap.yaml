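- icd_version: '10'
  prefix: C81
  group: HL
  is_HM: yes
  is_MM: no
- icd_version: '10'
  prefix: C82
  group: NHL
  is_HM: yes
  is_MM: no
- icd_version: '10'
  prefix: C83
  group: NHL
  is_HM: yes
  is_MM: no
- icd_version: '10'
  prefix: C833
  group: DLBCL
  is_HM: yes
  is_MM: no
- icd_version: '10'
  prefix: C84
  group: NHL
  is_HM: yes
  is_MM: no
- icd_version: '10'
  prefix: C85
  group: NHL
  is_HM: yes
  is_MM: no
- icd_version: '10'
  prefix: C86
  group: NHL
  is_HM: yes
  is_MM: no
- icd_version: '10'
  prefix: C88
  group: NHL
  is_HM: yes
  is_MM: no
- icd_version: '10'
  prefix: C90
  group: PCM
  is_HM: yes
  is_MM: no
- icd_version: '10'
  prefix: C91
  group: ALL_CLL
  is_HM: yes
  is_MM: no
- icd_version: '10'
  prefix: C92
  group: AML
  is_HM: yes
  is_MM: yes
- icd_version: '10'
  prefix: C93
  group: CMML
  is_HM: yes
  is_MM: yes
- icd_version: '10'
  prefix: C94
  group: OTHER_MYELOID
  is_HM: yes
  is_MM: yes
- icd_version: '10'
  prefix: C95
  group: LEUKEMIA_NOS
  is_HM: yes
  is_MM: no
- icd_version: '10'
  prefix: C96
  group: OTHER_HM
  is_HM: yes
  is_MM: no
- icd_version: '10'
  prefix: D45
  group: PV
  is_HM: yes
  is_MM: yes
- icd_version: '10'
  prefix: D46
  group: MDS
  is_HM: yes
  is_MM: yes
- icd_version: '10'
  prefix: D47
  group: OTHER_HM
  is_HM: yes
  is_MM: no
- icd_version: '10'
  prefix: D471
  group: MPN
  is_HM: yes
  is_MM: yes
- icd_version: '10'
  prefix: D473
  group: ET
  is_HM: yes
  is_MM: yes
- icd_version: '9'
  prefix: '200'
  group: NHL
  is_HM: yes
  is_MM: no
- icd_version: '9'
  prefix: '201'
  group: HL
  is_HM: yes
  is_MM: no
- icd_version: '9'
  prefix: '202'
  group: NHL
  is_HM: yes
  is_MM: no
- icd_version: '9'
  prefix: '203'
  group: PCM
  is_HM: yes
  is_MM: no
- icd_version: '9'
  prefix: '204'
  group: ALL_CLL
  is_HM: yes
  is_MM: no
- icd_version: '9'
  prefix: '205'
  group: AML
  is_HM: yes
  is_MM: yes
- icd_version: '9'
  prefix: '206'
  group: OTHER_MYELOID
  is_HM: yes
  is_MM: yes
- icd_version: '9'
  prefix: '207'
  group: OTHER_MYELOID
  is_HM: yes
  is_MM: yes
- icd_version: '9'
  prefix: '208'
  group: LEUKEMIA_NOS
  is_HM: yes
  is_MM: no
- icd_version: '9'
  prefix: '2387'
  group: OTHER_HM
  is_HM: yes
  is_MM: no
- icd_version: '9'
  prefix: '23872'
  group: MDS
  is_HM: yes
  is_MM: yes
- icd_version: '9'
  prefix: '23873'
  group: MDS
  is_HM: yes
  is_MM: yes
- icd_version: '9'
  prefix: '23874'
  group: MDS
  is_HM: yes
  is_MM: yes
- icd_version: '9'
  prefix: '23875'
  group: MDS
  is_HM: yes
  is_MM: yes
- icd_version: '9'
  prefix: '23876'
  group: MPN
  is_HM: yes
  is_MM: yes
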