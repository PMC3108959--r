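# Baseline material properties for interstitial fluid transport simulations
# (classic Jain & Baxter normal/tumor set; units cm, s, mmHg).
# Solid tumors carry no functional lymphatics: lymph_coeff = 0.
tissues:
  tumor:
    K: 4.13e-8        # interstitial hydraulic conductivity, cm^2/(mmHg s)
    Lp: 2.8e-7        # microvascular wall hydraulic conductivity, cm/(mmHg s)
    SV: 200.0         # vascular surface area per tissue volume, 1/cm
    pv: 15.6          # vascular pressure, mmHg
    sigma: 0.82       # osmotic reflection coefficient
    pi_v: 20.0        # plasma osmotic pressure, mmHg
    pi_i: 15.0        # interstitial osmotic pressure, mmHg
    lymph_coeff: 0.0  # lymphatic filtration coefficient, 1/(mmHg s)
    pL: 0.0           # lymphatic hydrostatic pressure, mmHg
  normal:
    K: 8.53e-9
    Lp: 3.6e-8
    SV: 70.0
    pv: 15.6
    sigma: 0.91
    pi_v: 20.0
    pi_i: 10.0
    lymph_coeff: 0.0
    pL: 0.0
geometry:
  R_cm: 1.0
  Rn_cm: 0.0
  R_out_cm: 3.0
  n_per_axis: 32
boundary:
  kind: isolated
  p_surr_mmHg: 0.0
  p_far_mmHg: 0.0
solver:
  method: direct
  tol: 1.0e-6
  relaxation: 0.75
  max_iter: 100000
  n_cells: 1000
analysis:
  eps: 0.01
  radii_cm: [0.1, 0.25, 0.5, 1.0]
  rn_bar: 0.0
output:
  prefix: ifpsim_run
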