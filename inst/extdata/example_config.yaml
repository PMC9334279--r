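# example simulation configuration: the in-vivo pulsing scheme with the
# bench transducer and default bone property mapping
sonication:
  ff_hz: 200000
  pd_s: 0.1
  prf_hz: 1
  duration_s: 1800
  ispta_w_cm2: 0.5
transducer:
  aperture_diameter_m: 0.028
  curvature_radius_m: 0.022
  position_m: [0.0, 0.0, 0.0]
  axis: [1.0, 0.0, 0.0]
skull_mapping:
  hu_soft_threshold: 300
  hu_max: 2000
  rho_bone_kg_m3: 2100
  c_bone_m_s: 2800
  alpha_min_np_m: 23
  alpha_max_np_m: 70
  beta: 0.5
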