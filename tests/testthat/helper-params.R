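# Parameter fixtures built in code.

# lymph-free tumor-like tissue whose alpha equals `alpha` at R = 1 cm and
# whose effective pressure is `pe` (sigma = 0 so p_e = pv)
make_alpha_params <- function(alpha, pe = 10, K = 1e-6) {
  tissue_parameters(K = K, Lp = K * alpha^2 / 200, SV = 200,
                    pv = pe, sigma = 0, pi_v = 0, pi_i = 0,
                    lymph_coeff = 0, pL = 0)
}

baseline_tumor <- baseline_tissue_parameters("tumor")
baseline_normal <- baseline_tissue_parameters("normal")

# sourceless tissue sharing the tumor conductivity (Laplace region)
sourceless_shell <- function(params) {
  tissue_parameters(K = params$K, Lp = 0, SV = 0, pv = params$pv,
                    sigma = params$sigma, pi_v = params$pi_v,
                    pi_i = params$pi_i, lymph_coeff = 0, pL = 0)
}

# small run configuration written to a temp file (YAML)
write_test_config <- function(path, N = 200, n_per_axis = 16, R_cm = 0.1,
                              Rn_cm = 0, R_out_cm = 0.15,
                              kind = "isolated", method = "direct") {
  cfg <- list(
    tissues = list(
      tumor = unclass(baseline_tumor)[c("K", "Lp", "SV", "pv", "sigma",
                                        "pi_v", "pi_i", "lymph_coeff", "pL")],
      normal = unclass(baseline_normal)[c("K", "Lp", "SV", "pv", "sigma",
                                          "pi_v", "pi_i", "lymph_coeff", "pL")]),
    geometry = list(R_cm = R_cm, Rn_cm = Rn_cm, R_out_cm = R_out_cm,
                    n_per_axis = n_per_axis),
    boundary = list(kind = kind, p_surr_mmHg = 0, p_far_mmHg = 0),
    solver = list(method = method, tol = 1e-8, relaxation = 0.75,
                  max_iter = 100000L, n_cells = N),
    analysis = list(eps = 0.01, radii_cm = c(0.1, 0.25, 0.5, 1.0), rn_bar = 0),
    output = list(prefix = "test_run"))
  yaml::write_yaml(cfg, path)
  path
}
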