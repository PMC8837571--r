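# Default HPA-axis wiring: stress -> CRH -> ACTH -> COR -> GR, GR -| CRH/ACTH,
# CRH and GR self-activation. Numeric weights and sampling ranges are a
# documented reconstruction (see the methods vignette), not published values.
species:
- CRH
- ACTH
- COR
- GR
sigma: 1.0
k:
  CRH: 1.0
  ACTH: 1.0
  COR: 1.0
  GR: 1.0
r0:
  CRH: -2.0
  ACTH: -2.0
  COR: -2.0
  GR: -3.0
stress_coupling:
  CRH: 1.0
  ACTH: 0.0
  COR: 0.0
  GR: 0.0
influences:
- source: CRH
  target: CRH
  weight: 3.0
- source: GR
  target: CRH
  weight: -4.0
- source: CRH
  target: ACTH
  weight: 4.0
- source: GR
  target: ACTH
  weight: -4.0
- source: ACTH
  target: COR
  weight: 4.0
- source: COR
  target: GR
  weight: 2.0
- source: GR
  target: GR
  weight: 3.0
protocol:
  baseline: 0.1
  t_on: 10.0
  t_peak: 15.0
  rate: 0.6
ranges:
  k_CRH:
  - 1.0
  - 10.0
  k_ACTH:
  - 1.0
  - 10.0
  k_COR:
  - 1.0
  - 10.0
  k_GR:
  - 1.0
  - 10.0
  R0_CRH:
  - -4.0
  - 0.0
  R0_ACTH:
  - -4.0
  - 0.0
  R0_COR:
  - -4.0
  - 0.0
  R0_GR:
  - -4.0
  - 0.0
  R_CRH_CRH:
  - 0.0
  - 8.0
  R_GR_GR:
  - 0.0
  - 8.0
  R_CRH_ACTH:
  - 0.0
  - 8.0
  R_ACTH_COR:
  - 0.0
  - 8.0
  R_COR_GR:
  - 0.0
  - 8.0
  R_GR_CRH:
  - -8.0
  - 0.0
  R_GR_ACTH:
  - -8.0
  - 0.0
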