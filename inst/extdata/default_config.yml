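# Standards, thresholds and exposure-factor model for Hg/As assessment of a
# seasonally frozen lake. All values are data: nothing here is hard-coded in
# package operations.
standards:
  Hg:
    si_ug_L: 1        # irrigation water quality limit (GB5084-2021)
    bn_mg_kg: 0.025   # regional sediment background
    tel_mg_kg: 0.17
    pel_mg_kg: 0.48
  As:
    si_ug_L: 50
    bn_mg_kg: 9.68
    tel_mg_kg: 5.90
    pel_mg_kg: 17.0
  k_background: 1.5   # natural-fluctuation constant in the geo-accumulation index
toxicity:
  rfd_mg_kg_d:
    Hg: 0.0003
  sf_kg_d_mg:
    As: 1.5
thresholds:
  cr_acceptable: 1.0e-4
  hq_acceptable: 1.0
deterministic_exposure:
  adult:
    IR: 2.0           # L/d
    EF: 365           # d/a
    ED_carcinogenic: 70      # a
    ED_noncarcinogenic: 70
    BW: 66.1          # kg
    AT_carcinogenic: 25550   # d
    AT_noncarcinogenic: 25550
  child:
    IR: 1.0           # L/d; 0.7 L/d is an available override (see docs)
    EF: 365
    ED_carcinogenic: 70
    ED_noncarcinogenic: 10
    BW: 22.9
    AT_carcinogenic: 25550
    AT_noncarcinogenic: 3650
probabilistic_exposure:
  adult:
    BW: {kind: lognormal, mean: 59.78, sd: 1.07}    # kg, arithmetic moments
    IR: {kind: lognormal, mean: 1.23, sd: 0.27}     # L/d
    ED: {kind: uniform, min: 0, max: 70}            # a
    EF: {kind: triangular, min: 180, mode: 350, max: 365}  # d/a
    AT_carcinogenic: {kind: point, value: 25550}    # d
    AT_noncarcinogenic: {kind: point, value: 25550}
  child:
    BW: {kind: lognormal, mean: 16.68, sd: 1.48}
    IR: {kind: lognormal, mean: 1.12, sd: 0.27}
    ED: {kind: uniform, min: 0, max: 10}
    EF: {kind: triangular, min: 180, mode: 350, max: 365}
    AT_carcinogenic: {kind: point, value: 25550}
    AT_noncarcinogenic: {kind: point, value: 3650}
concentration_distributions:
  - {element: Hg, medium: ice,   kind: lognormal, mean: 7.90, sd: 4.35, unit: ng/L}
  - {element: As, medium: ice,   kind: lognormal, mean: 2.48, sd: 3.22, unit: ug/L}
  - {element: Hg, medium: water, kind: lognormal, mean: 0.37, sd: 0.23, unit: ug/L}
  - {element: As, medium: water, kind: lognormal, mean: 5.72, sd: 1.70, unit: ug/L}
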