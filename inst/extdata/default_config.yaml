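# Baseline model configuration. Field names mirror the published parameter
# table; values are the healthy-population defaults.
population:
  r_CRA:  {mean: 81.0, sd: 8.0}     # um
  v_CRA:  {mean: 6.3,  sd: 1.2}     # cm/s
  MAP:    {mean: 84.0, sd: 6.0}     # mmHg
  IOP:    {mean: 11.1, sd: 2.1}     # mmHg
  crv_cra_radius_ratio: 1.11
  cra_length: 10.0     # mm, modelled CRA/CRV feeding-segment length

domain:
  r_retina: 15.0       # mm, modelled region radius (fovea-centred)
  r_perifovea: 3.0     # mm, macular region radius
  r_parafovea: 1.5     # mm
  r_FAZ: 0.25          # mm, foveal avascular zone
  disc_x: -4.5         # mm, optic disc centre (left-eye orientation)
  disc_y: 0.0

stages:                # constructive-optimization stages, in growth order
  - {N_terms: 200, p_pre_capillary: 30.0, delta: 0.8, theta_min: 60.0,
     gamma: 3.0,  l_fr: 0.8, nu: 1.0, f_n: 1.0, region: full}
  - {N_terms: 150, p_pre_capillary: 23.0, delta: 0.0, theta_min: 60.0,
     gamma: 2.85, l_fr: 0.5, nu: 1.0, f_n: 1.0, region: annulus}
  - {N_terms: 75,  p_pre_capillary: 23.0, delta: 0.0, theta_min: 60.0,
     gamma: 2.85, l_fr: 0.5, nu: 1.0, f_n: 1.0, region: parafovea}

terminal_site:         # fovea-biased radial law r = r0 + exp(mu + sigma*Z)
  sigma: 4.0
  mu: -0.5
  r0: 0.02

growth:
  eta: 0.36            # cP, viscosity fixed-point starting value
  n_candidates: 20     # host segments tried per insertion
  max_attempts: 10000

plexus:
  SVP: {N_seeds: 5500,  r_capillary: 2.5, z: 0}
  ICP: {N_seeds: 16000, r_capillary: 2.5, z: 135}
  DCP: {N_seeds: 10500, r_capillary: 2.5, z: 180}
  alpha: 0.4           # fraction of macular arterioles/venules wired to bed
  frac_deep: 0.3       # fraction bifurcating to the ICP (then DCP)

hemo:
  R_compartment: 1.0e+6 # mmHg*s/mL, artificial closure resistance
  H_D: 0.45            # discharge hematocrit
  mu_plasma: 1.0       # cP, scaling of the relative viscosity law

shape_model:
  n_landmarks: 20
  n_components: 5
  n_training_eyes: 8
  clamp_sd: 3.0

morphometrics:
  fov_diameter: 3.0    # mm, analysis disk
  px_size: 10.0        # um per pixel
  ivd_factor: 2.0      # IVD = factor * mean background EDT
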