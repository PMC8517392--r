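nc:
  label: NC
  'n': 50
  covariates:
    age:
      dist: normal
      mean: 46.88
      sd: 10.6
      lower: 18.0
      upper: 80.0
    male:
      dist: bernoulli
      p: 0.58
    smoking:
      dist: bernoulli
      p: 0.24
    bmi:
      dist: normal
      mean: 24.32
      sd: 3.67
      lower: 15.0
      upper: 45.0
    bsa:
      dist: normal
      mean: 1.72
      sd: 0.16
      lower: 1.2
      upper: 2.6
    sbp_mmhg:
      dist: normal
      mean: 118.84
      sd: 3.94
      lower: 90.0
      upper: 140.0
    dbp_mmhg:
      dist: normal
      mean: 77.7
      sd: 6.31
      lower: 50.0
      upper: 90.0
    heart_rate:
      dist: normal
      mean: 67.82
      sd: 8.37
      lower: 45.0
      upper: 110.0
    tc:
      dist: normal
      mean: 4.33
      sd: 0.61
      lower: 1.5
      upper: 9.0
    tg:
      dist: normal
      mean: 1.65
      sd: 0.64
      lower: 0.2
      upper: 8.0
    hdl_c:
      dist: lognormal
      median: 1.01
      iqr: 0.3
      upper: 4.0
    ldl_c:
      dist: normal
      mean: 2.48
      sd: 0.7
      lower: 0.5
      upper: 7.0
    hba1c:
      dist: normal
      mean: 5.24
      sd: 0.36
      lower: 4.0
      upper: 15.0
    lvef:
      dist: normal
      mean: 63.0
      sd: 2.5
      lower: 55.0
      upper: 72.0
  phenotype:
    peak_strain_pct: -19.5
    work_scale_sd: 0.091
    effect_hba1c: 0.0
    effect_duration: 0.0
    seg_sd: 0.08
    recovery_frac: 0.15
    recovery_sd: 0.04
    noise_sd: 1.1
    pss_prob: 0.15
    pss_sd: 1.5
    timing:
      ivc:
        mean: 0.06
        sd: 0.008
      ej:
        mean: 0.3
        sd: 0.02
      ivr:
        mean: 0.08
        sd: 0.01
    frame_rate: 65.0
dm:
  label: T2DM
  'n': 50
  covariates:
    age:
      dist: normal
      mean: 50.2
      sd: 9.73
      lower: 18.0
      upper: 80.0
    male:
      dist: bernoulli
      p: 0.52
    smoking:
      dist: bernoulli
      p: 0.28
    bmi:
      dist: normal
      mean: 26.09
      sd: 3.8
      lower: 15.0
      upper: 45.0
    bsa:
      dist: normal
      mean: 1.83
      sd: 0.24
      lower: 1.2
      upper: 2.6
    sbp_mmhg:
      dist: normal
      mean: 120.68
      sd: 6.0
      lower: 90.0
      upper: 140.0
    dbp_mmhg:
      dist: normal
      mean: 79.24
      sd: 7.4
      lower: 50.0
      upper: 90.0
    heart_rate:
      dist: normal
      mean: 71.02
      sd: 9.41
      lower: 45.0
      upper: 110.0
    tc:
      dist: normal
      mean: 4.5
      sd: 1.01
      lower: 1.5
      upper: 9.0
    tg:
      dist: normal
      mean: 2.17
      sd: 1.04
      lower: 0.2
      upper: 8.0
    hdl_c:
      dist: lognormal
      median: 1.03
      iqr: 0.23
      upper: 4.0
    ldl_c:
      dist: normal
      mean: 2.79
      sd: 0.66
      lower: 0.5
      upper: 7.0
    hba1c:
      dist: normal
      mean: 8.06
      sd: 1.37
      lower: 4.0
      upper: 15.0
    lvef:
      dist: normal
      mean: 63.0
      sd: 2.5
      lower: 55.0
      upper: 72.0
    fpg:
      dist: normal
      mean: 7.88
      sd: 1.49
      lower: 3.5
      upper: 20.0
    ppg_2h:
      dist: normal
      mean: 11.6
      sd: 2.32
      lower: 4.0
      upper: 28.0
    duration_yr:
      dist: lognormal
      median: 2.5
      iqr: 9.37
      upper: 40.0
  phenotype:
    peak_strain_pct: -17.0
    work_scale_sd: 0.1378
    effect_hba1c: -0.45
    effect_duration: -0.3
    seg_sd: 0.08
    recovery_frac: 0.15
    recovery_sd: 0.04
    noise_sd: 1.0
    pss_prob: 0.4
    pss_sd: 2.0
    timing:
      ivc:
        mean: 0.06
        sd: 0.008
      ej:
        mean: 0.29
        sd: 0.02
      ivr:
        mean: 0.08
        sd: 0.01
    frame_rate: 65.0

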