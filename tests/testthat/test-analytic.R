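# Closed-form solutions, cross-checked against the independent node-centered
# finite-difference oracle (helper-oracle.R) and against each other.

test_that("uniform isolated solution matches its center value and the FD oracle", {
  # frozen values computed from 1 - alpha/sinh(alpha)
  expect_equal(center_pressure(1), 0.1490818717606784, tolerance = 1e-12)
  expect_equal(center_pressure(10), 0.9990920014028788, tolerance = 1e-12)
  for (alpha in c(1, 10)) {
    fd <- fd_dimensionless_oracle(alpha, n = 10000)
    prof <- solve_isolated_uniform(alpha, fd$r)
    expect_lt(max(abs(prof$P - fd$p)), 1e-6)
  }
  # Dirichlet rim for a range of alphas
  for (alpha in c(0.5, 1, 5, 10, 33, 50))
    expect_equal(solve_isolated_uniform(alpha, c(0, 1))$P[2], 0)
  expect_error(solve_isolated_uniform(-1), "alpha")
  expect_error(solve_isolated_uniform(2, c(-0.1, 0.5)), "rbar_grid")
})

test_that("closed form satisfies the governing equation at interior points", {
  # residual of (1/r^2)(r^2 P')' - alpha^2 (P - 1) via high-order numerical
  # differentiation of the closed form
  for (alpha in c(1, 8)) {
    Pfun <- function(r) solve_isolated_uniform(alpha, r)$P
    r0 <- seq(0.15, 0.85, by = 0.1)
    h <- 1e-3
    # five-point stencils for P' and P''
    P <- sapply(-2:2, function(k) Pfun(r0 + k * h))
    P1 <- (P[, 1] - 8 * P[, 2] + 8 * P[, 4] - P[, 5]) / (12 * h)
    P2 <- (-P[, 1] + 16 * P[, 2] - 30 * P[, 3] + 16 * P[, 4] - P[, 5]) / (12 * h^2)
    resid <- P2 + 2 / r0 * P1 - alpha^2 * (Pfun(r0) - 1)
    expect_lt(max(abs(resid)), 1e-8)
  }
})

test_that("monotonicity and limit behaviour of the uniform solution", {
  prof <- solve_isolated_uniform(7, seq(0, 1, length.out = 400))
  expect_true(all(diff(prof$P) <= 1e-14))           # non-increasing in r
  expect_true(all(prof$U >= 0))                     # radially outward
  alphas <- c(0.5, 1, 2, 5, 10, 20, 40)
  expect_true(all(diff(center_pressure(alphas)) > 0))  # increasing in alpha
  expect_gt(center_pressure(200), 1 - 1e-10)        # P(0) -> 1 (p_e) at large alpha
})

test_that("rim velocity equals alpha*coth(alpha)-1 and the derivative of P", {
  expect_equal(rim_velocity_dimensionless(1), 0.313035285499331,
               tolerance = 1e-12)  # frozen closed-form value at alpha = 1
  expect_equal(rim_velocity_dimensionless(3), 3 / tanh(3) - 1, tolerance = 1e-14)
  expect_equal(rim_velocity_dimensionless(50), 50 - 1, tolerance = 1e-10)
  expect_lt(rim_velocity_dimensionless(1e-3), 1e-5)  # no-vasculature limit
  # oracle: numerical derivative of P at the rim
  h <- 1e-6
  for (alpha in c(2, 12)) {
    dP <- (solve_isolated_uniform(alpha, 1)$P -
             solve_isolated_uniform(alpha, 1 - h)$P) / h
    expect_equal(rim_velocity_dimensionless(alpha), -dP, tolerance = 1e-4)
  }
})

test_that("necrotic-core solution reduces, vanishes and matches the FD oracle", {
  grid <- seq(0, 1, length.out = 501)
  # fully necrotic tumor: zero pressure everywhere
  expect_equal(max(abs(solve_necrotic(5, 1, grid)$P)), 0)
  # no core: identical to the uniform solution
  d <- solve_necrotic(3, 0, grid)$P - solve_isolated_uniform(3, grid)$P
  expect_lt(max(abs(d)), 1e-12)
  # independent oracle at alpha = 10, rn = 0.5
  fd <- fd_dimensionless_oracle(10, rn_bar = 0.5, n = 10000)
  prof <- solve_necrotic(10, 0.5, fd$r)
  expect_lt(abs(prof$P[1] - fd$p[1]), 1e-4)
  expect_lt(max(abs(prof$P - fd$p)), 1e-4)
  expect_error(solve_necrotic(10, 1.2), "rn_bar")
})

test_that("necrotic solution is continuous with a flat, flow-free core", {
  alpha <- 8; rn <- 0.4
  eps <- 1e-9
  prof <- solve_necrotic(alpha, rn, c(0, rn - eps, rn + eps, 1))
  expect_equal(prof$P[2], prof$P[3], tolerance = 1e-7)   # pressure continuity
  expect_equal(prof$P[1], prof$P[2], tolerance = 1e-12)  # constant core
  expect_equal(prof$U[1], 0)                             # no flow in the core
  expect_lt(abs(prof$U[3]), 1e-6)                        # flux -> 0 at the core edge
})

test_that("center pressure is non-increasing in the necrotic radius", {
  rns <- seq(0, 1, length.out = 50)
  for (alpha in c(2, 10, 36.8)) {
    P0 <- center_pressure(alpha, rns)
    expect_true(all(diff(P0) <= 1e-14))
    # agrees with the full profile solve
    expect_equal(P0[20], solve_necrotic(alpha, rns[20], c(0, 1))$P[1],
                 tolerance = 1e-12)
  }
})

test_that("embedded two-region solution obeys the interface and boundary conditions", {
  R <- 1.4; R_out <- 4.2
  prof <- solve_embedded(baseline_tumor, baseline_normal, R, R_out, p_far = 0)
  it <- max(which(prof$region == "tumor"))
  expect_equal(prof$p_mmHg[it], prof$p_mmHg[it + 1])       # pressure continuity
  expect_equal(prof$u_cm_per_s[it], prof$u_cm_per_s[it + 1],
               tolerance = 1e-12)                          # Darcy-flux continuity
  expect_equal(prof$p_mmHg[nrow(prof)], 0)                 # far-field Dirichlet
  # maximum principle: p between min/max of {p_far, p_e values}
  bounds <- range(0, effective_pressure(baseline_tumor),
                  effective_pressure(baseline_normal))
  expect_true(all(prof$p_mmHg >= bounds[1] - 1e-9))
  expect_true(all(prof$p_mmHg <= bounds[2] + 1e-9))
})

test_that("embedded solution matches the fine-grid two-region FD oracle", {
  R <- 1.4; R_out <- 4.2
  # n chosen so the tumor interface falls exactly on an oracle node
  fd <- fd_two_region_oracle(baseline_tumor, baseline_normal, R, R_out,
                             n = 30000)
  prof <- solve_embedded(baseline_tumor, baseline_normal, R, R_out,
                         p_far = 0, n = 40000)
  f <- suppressWarnings(stats::approxfun(prof$r_cm, prof$p_mmHg))
  expect_lt(max(abs(fd$p - f(fd$r))) / max(abs(fd$p)), 1e-4)
  # elevated, near-flat inside the tumor; decaying outside
  expect_gt(prof$p_mmHg[1], 0.99 * effective_pressure(baseline_tumor))
  outer_half <- prof$region == "normal" & prof$r_cm > (R + R_out) / 2
  expect_true(all(abs(prof$p_mmHg[outer_half]) <
                    abs(effective_pressure(baseline_normal)) + 1e-9))
})

test_that("embedded solve reduces to one region for identical parameters", {
  # same tissue on both sides, no lymphatics: the interface is immaterial and
  # the solution is the uniform isolated profile over the whole domain
  tum <- make_alpha_params(6)      # alpha 6 at R = 1
  prof <- solve_embedded(tum, tum, R = 0.5, R_out = 1, p_far = 0)
  ref <- solve_isolated_uniform(6, prof$r_cm)   # R_out = 1 so rbar = r
  pe <- effective_pressure(tum)
  expect_lt(max(abs(prof$p_mmHg - pe * ref$P)), 1e-9 * pe)
  expect_error(solve_embedded(tum, tum, R = 1, R_out = 0.5), "R_out")
})
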