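# Radial finite-volume solver against the closed forms and its own
# conservation/consistency contracts.

test_that("radial grids snap region boundaries onto faces", {
  g <- build_radial_grid(R = 1, Rn = 0, R_out = 1, N = 10)
  expect_length(g$faces, 11)
  expect_equal(range(g$faces), c(0, 1))
  expect_true(all(g$region == "tumor"))

  g2 <- build_radial_grid(R = 1, Rn = 0.5, N = 10)
  expect_true(any(abs(g2$faces - 0.5) == 0))        # face exactly at Rn
  expect_equal(sum(g2$region == "necrotic"), 5)

  g3 <- build_radial_grid(R = 1, Rn = 0.3, R_out = 2.4, N = 100)
  expect_true(all(c(0.3, 1) %in% g3$faces))
  expect_true(all(diff(g3$faces) > 0))
  expect_equal(g3$N, 100)
  # labels consistent with radii
  expect_true(all(g3$centers[g3$region == "necrotic"] < 0.3))
  expect_true(all(g3$centers[g3$region == "normal"] > 1))

  expect_error(build_radial_grid(R = 1, Rn = 0.5, R_out = 1.5, N = 2), "N")
  expect_error(build_radial_grid(R = 1, Rn = 2), "Rn")
})

test_that("degenerate sources give exact constant solutions", {
  tum <- make_alpha_params(4)
  # fully necrotic tumor with zero surrounding pressure: p identically 0
  g <- build_radial_grid(R = 1, Rn = 1, N = 50)
  sol <- solve_radial(g, list(tumor = tum), p_out = 0)
  expect_equal(max(abs(sol$p)), 0)
  # zero source, nonzero Dirichlet: constant solution of the Laplace problem
  sol2 <- solve_radial(g, list(tumor = tum), p_out = 4.5)
  expect_lt(max(abs(sol2$p - 4.5)), 1e-12)
})

test_that("radial solve matches the closed form at N = 1000", {
  for (alpha in c(1, 10)) {
    tum <- make_alpha_params(alpha)
    g <- build_radial_grid(R = 1, N = 1000)
    sol <- solve_radial(g, list(tumor = tum), p_out = 0)
    Pn <- sol$p / effective_pressure(tum)
    expect_lt(max(abs(Pn - solve_isolated_uniform(alpha, g$centers)$P)), 1e-4)
    expect_lt(sol$report$conservation_gap, 1e-10)
  }
})

test_that("necrotic and embedded radial solves match their closed forms", {
  tum <- make_alpha_params(10)
  g <- build_radial_grid(R = 1, Rn = 0.5, N = 1000)
  sol <- solve_radial(g, list(tumor = tum), p_out = 0)
  ref <- solve_necrotic(10, 0.5, g$centers)
  expect_lt(max(abs(sol$p / 10 - ref$P)), 1e-4)

  g2 <- build_radial_grid(R = 1.4, R_out = 4.2, N = 3000)
  sol2 <- solve_radial(g2, list(tumor = baseline_tumor,
                                normal = baseline_normal), p_out = 0)
  ref2 <- solve_embedded(baseline_tumor, baseline_normal, 1.4, 4.2,
                         p_far = 0, n = 60000)
  f <- suppressWarnings(stats::approxfun(ref2$r_cm, ref2$p_mmHg))
  expect_lt(max(abs(sol2$p - f(g2$centers))) / max(abs(sol2$p)), 2e-4)
})

test_that("solution respects the maximum principle", {
  tum <- baseline_tumor
  g <- build_radial_grid(R = 0.5, N = 400)
  for (p_out in c(0, 3)) {
    sol <- solve_radial(g, list(tumor = tum), p_out = p_out)
    expect_true(all(sol$p >= min(p_out, 11.5) - 1e-12))
    expect_true(all(sol$p <= max(p_out, 11.5) + 1e-12))
  }
})

test_that("SOR sweeps converge to the direct solution", {
  tum <- make_alpha_params(5)
  g <- build_radial_grid(R = 1, N = 80)
  direct <- solve_radial(g, list(tumor = tum), p_out = 0)
  sor <- solve_radial(g, list(tumor = tum), p_out = 0, method = "sor",
                      tol = 1e-10)
  expect_true(sor$report$converged)
  expect_lt(max(abs(direct$p - sor$p)) / max(abs(direct$p)), 1e-6)
  expect_gt(sor$report$iterations, 1)
  # under-relaxation mirrors the reference implementation; over-relaxation
  # is accepted too
  sor2 <- solve_radial(g, list(tumor = tum), p_out = 0, method = "sor",
                       tol = 1e-10, relaxation = 1.5)
  expect_lt(max(abs(direct$p - sor2$p)) / max(abs(direct$p)), 1e-6)
})

test_that("face velocities follow Darcy's law and the analytic rim speed", {
  tum <- make_alpha_params(1)
  g <- build_radial_grid(R = 1, N = 1000)
  sol <- solve_radial(g, list(tumor = tum), p_out = 0)
  vel <- darcy_velocity(sol)
  expect_equal(vel$u_cm_per_s[1], 0)                 # symmetry at the center
  expect_true(all(vel$u_cm_per_s >= 0))              # radially outward
  u_exact <- tum$K * 10 / 1 * rim_velocity_dimensionless(1)
  expect_equal(vel$u_cm_per_s[g$N + 1], u_exact, tolerance = 1e-3)
  expect_equal(sol$report$rim_velocity_cm_per_s, u_exact, tolerance = 1e-3)
  # uniform pressure (zero-source Laplace solve) has zero velocity
  g0 <- build_radial_grid(R = 1, Rn = 1, N = 50)
  sol0 <- solve_radial(g0, list(tumor = tum), p_out = 2)
  expect_lt(max(abs(darcy_velocity(sol0)$u_cm_per_s)), 1e-15)
})

test_that("profile export carries the dimensionless and dimensional views", {
  tum <- make_alpha_params(3, pe = 8)
  sol <- solve_radial(build_radial_grid(R = 0.5, N = 300),
                      list(tumor = tum), p_out = 0)
  prof <- as_profile(sol)
  expect_named(prof, c("rbar", "r_cm", "P", "p_mmHg", "U", "u_cm_per_s",
                       "u_um_per_s", "phiB_per_s"))
  expect_equal(prof$p_mmHg, 8 * prof$P)
  expect_equal(prof$u_um_per_s, prof$u_cm_per_s * 1e4)
  expect_equal(prof$phiB_per_s, starling_source(tum, prof$p_mmHg))
})
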