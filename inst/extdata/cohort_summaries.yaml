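# Per-group cohort summaries: mean and SEM for each clinical / CTA
# morphometric variable, with group sizes.  Units: age months, weight kg,
# PSPG mmHg, angles degrees; diameter ratios and A/T dimensionless.
# Categorical counts: gender_m = male cases, pda = patent ductus arteriosus.
groups:
  gothic:
    "n": 27
    gender_m: 12
    pda: 19
    variables:
      age:     {mean: 14.3444, sem: 5.64625}
      weight:  {mean: 6.996,   sem: 0.9809}
      pspg:    {mean: 38.585,  sem: 3.5754}
      D1_AOA:  {mean: 0.6304,  sem: 0.02607}
      D2_AOA:  {mean: 0.5344,  sem: 0.02710}
      D3_AOA:  {mean: 0.2896,  sem: 0.02266}
      D4_AOA:  {mean: 0.7098,  sem: 0.02982}
      D5_AOA:  {mean: 0.6414,  sem: 0.02788}
      AAO_DAO: {mean: 26.74,   sem: 1.578}
      TAO_DAO: {mean: 109.81,  sem: 1.716}
      A_T:     {mean: 0.70148, sem: 0.014898}
  crenel:
    "n": 25
    gender_m: 17
    pda: 18
    variables:
      age:     {mean: 5.0307,  sem: 1.93247}
      weight:  {mean: 4.808,   sem: 0.5305}
      pspg:    {mean: 43.076,  sem: 3.4719}
      D1_AOA:  {mean: 0.6923,  sem: 0.03201}
      D2_AOA:  {mean: 0.5614,  sem: 0.02282}
      D3_AOA:  {mean: 0.3078,  sem: 0.02511}
      D4_AOA:  {mean: 0.8404,  sem: 0.04272}
      D5_AOA:  {mean: 0.7731,  sem: 0.04082}
      AAO_DAO: {mean: 34.56,   sem: 1.791}
      TAO_DAO: {mean: 112.40,  sem: 2.106}
      A_T:     {mean: 0.49028, sem: 0.013728}
  romanesque:
    "n": 43
    gender_m: 25
    pda: 35
    variables:
      age:     {mean: 6.7548,  sem: 1.78188}
      weight:  {mean: 5.451,   sem: 0.4003}
      pspg:    {mean: 38.557,  sem: 2.4324}
      D1_AOA:  {mean: 0.6646,  sem: 0.02213}
      D2_AOA:  {mean: 0.5634,  sem: 0.02092}
      D3_AOA:  {mean: 0.3764,  sem: 0.01492}
      D4_AOA:  {mean: 0.7729,  sem: 0.02893}
      D5_AOA:  {mean: 0.7292,  sem: 0.02083}
      AAO_DAO: {mean: 31.88,   sem: 0.941}
      TAO_DAO: {mean: 108.57,  sem: 0.936}
      A_T:     {mean: 0.58212, sem: 0.012791}
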