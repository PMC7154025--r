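# Default configuration of the pulse-duplicator twin.
# Units: pressure mmHg (tissue stresses kPa/MPa), length cm, time s,
# flow mL/s, resistance mmHg s/mL, compliance mL/mmHg.
hr_bpm: 70

test_section:
  diameter_cm: 2.8
  length_cm: 10.1

fluid:
  saline:          {rho: 1.0, mu: 1.0}
  blood_analogue:  {rho: 1.0, mu: 3.5}

material:
  beta_mpa: 14.1
  porcine:
    c10_kpa: 0.302
    c01: 3.25
    k1_mpa: 0.197
    k2: 0.001
    kappa: 0.0
    fiber_angle_deg: 0
  pericardial:
    c10_kpa: 0.119
    c01: 22.59
    k1_mpa: 2.38
    k2: 149.8
    kappa: 0.292
    fiber_angle_deg: 45

wall:
  c_wall_kpa: 33.1
  kappa_wall_mpa_cm2: 852

circuit:
  porcine:
    upstream:   {r1: 0.15, r2: 0.15, c_via: 0.1}
    downstream: {r_c: 0.0218, r_p: 1.31, c: 0.915}
    c_lv: 0.02
  pericardial:
    upstream:   {c_via1: 0.0275, c_via2: 0.0347, r_via: 0.15,
                 r_out: 0.0898, r_mv: 0.0280, r_out_node: v1}
    downstream: {r_c: 0.0282, r_p: 1.22, c: 1.27}

valve:
  k_open: 5.0        # 1/(mmHg s)
  k_close: 5.0
  inertance: 5.0e-4  # mmHg s^2/mL
  leak_frac: 0.001   # a_leak / a_max
  discharge_coeff: 0.7
  porcine:
    q_peak_ml_s: 452.5       # implied by Re_peak 20576, D 2.8 cm, saline
    dp_sim_mmhg: 22.4        # simulated peak forward gradient
    cap_radius_cm: 1.25
    thickness_cm: 0.04
    material: porcine
  pericardial:
    q_peak_ml_s: 425.1       # implied by Re_peak 19330
    dp_sim_mmhg: 16.4
    cap_radius_cm: 1.25
    thickness_cm: 0.04
    material: pericardial

experiment:
  n_cycles: 10
  filter_cutoff_hz: 100
  pdva_flutter: {freq_hz: 40, amp_frac: 0.04, decay_s: 0.06}
  sensor_noise: {pressure_mmhg: 0.1, flow_ml_s: 1.0, pdva_cm2: 0.01}
  porcine:
    sv_mean_ml: 69.4
    sv_sd_ml: 0.4
    dp_mean_mmhg: 22.8
    dp_sd_mmhg: 0.2
    q_peak_ml_s: 452.5
    filter_pressure: true    # customized platform filters flow and pressure
    filter_flow: true
  pericardial:
    sv_mean_ml: 71.6
    sv_sd_ml: 0.7
    dp_mean_mmhg: 19.7
    dp_sd_mmhg: 0.5
    q_peak_ml_s: 425.1
    filter_pressure: false   # FDA platform leaves pressures unfiltered
    filter_flow: true

driver_init:
  porcine:     {base: 8.0, amp: 250.0, width: 0.26}
  pericardial: {amp: 470.0, width: 0.26, p_la: 9.0}

integration:
  dt_out: 1.0e-3
  hmax: 1.0e-3
  tol: 1.0e-4
  max_cycles: 60
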