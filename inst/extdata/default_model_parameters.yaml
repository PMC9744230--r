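# Default constants of the glucose-insulin-exocytosis model.
# Single source of all fixed (non-estimated) constants; sigma and S_I are the
# two estimated parameters and carry placeholders here.
model_version: 1

# estimated parameters (placeholders; overwritten per patient / per MCMC draw)
S_I: 0.3       # insulin sensitivity, day^-1 per uIU/mL (model-native scale)
sigma: 3.0     # maximal insulin secretion capacity, unitless

# fixed scalars
gamma: -0.076      # K+-ATP channel density, unitless (fixed on OGTT timescale)
E_G0: 0.0118       # insulin-independent glucose effectiveness, min^-1
si_scale: 6.944444444444445e-4  # 1/1440: S_I day^-1 -> min^-1
k: 0.15            # insulin clearance rate, min^-1
V: 10.0            # insulin volume of distribution, L
beta: 58.5         # beta-cell mass, fixed scalar (enters as beta/V)
hepa_SI: 1.0       # hepatic insulin sensitivity, fixed
r2_0: 0.02         # baseline vesicle priming rate, min^-1

# exocytosis coefficient functions C_{i,j}(G, gamma, sigma, r2_0), C_ISR(G, gamma)
exo_coeffs:
  cisr_max: 0.05       # maximal fusion (secretion) rate, min^-1
  K_half: 150.0        # glucose half-activation of the Ca-sensing sigmoid, mg/dL
  K_slope: 30.0        # slope of the sigmoid, mg/dL
  r2_base: 0.1         # glucose-independent floor of the priming rate (x r2_0)
  r_unprime: 0.01      # unpriming N5 -> N6, min^-1 (the constant c_6_5)
  r_undock: 0.01       # undocking loss from N6, min^-1
  dock_base: 0.2       # glucose-independent docking influx (x sigma), vesicles/min
  dock_max: 2.0        # glucose-stimulated docking influx (x sigma), vesicles/min

# hepatic glucose production HGP(I) = hgp_max / (1 + hepa_SI * (I/I_half)^h_pow)
hgp_coeffs:
  hgp_max: 1.67        # plateau at I = 0, mg/dL/min (re-anchored at fasting state)
  I_half: 30.0         # insulin half-suppression scale, uIU/mL
  h_pow: 1.5           # Hill exponent, dimensionless

# oral glucose appearance: gamma-density-shaped rate
ogtt_input:
  dose_g: 75.0             # ingested glucose, g
  absorbed_fraction: 0.8   # fraction reaching plasma over [0, Inf)
  glucose_vol_dl: 180.0    # glucose distribution volume, dL (converts mg -> mg/dL)
  appearance_shape: 3.0    # gamma-density shape; peak at (shape-1)*scale
  appearance_peak_min: 30.0  # mode of the appearance curve, min
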