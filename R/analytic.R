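# Closed-form spherically symmetric solutions of the interstitial pressure
# equation  (1/r^2) d/dr (r^2 dP/dr) = alpha^2 (P - 1)  on the unit ball
# (dimensionless form; P = (p - p_surr)/(p_e - p_surr), rbar = r/R), with a
# symmetry condition at the center and P = 0 at the rim, plus the necrotic-core
# (Laplace) and embedded (two-region) variants.
#
# Hyperbolic terms are evaluated through ratios of the form
# sinh(a*x)/sinh(a) = exp(a*(x-1)) * (1 - exp(-2*a*x))/(1 - exp(-2*a)),
# which stay finite for arbitrarily large a, with series expansions at the
# removable singularity rbar -> 0 (no small-epsilon offsets).

# sinh(alpha*rbar)/sinh(alpha), vectorised in rbar; alpha > 0
.sinh_ratio <- function(alpha, rbar) {
  exp(alpha * (rbar - 1)) * (-expm1(-2 * alpha * rbar)) / (-expm1(-2 * alpha))
}

# cosh(alpha*rbar)/sinh(alpha)
.cosh_ratio <- function(alpha, rbar) {
  exp(alpha * (rbar - 1)) * (1 + exp(-2 * alpha * rbar)) / (-expm1(-2 * alpha))
}

# P and U = -dP/drbar for the uniform (non-necrotic) isolated sphere
.uniform_PU <- function(alpha, rbar) {
  P <- U <- numeric(length(rbar))
  small <- alpha * rbar < 1e-4
  if (any(!small)) {
    r <- rbar[!small]
    s <- .sinh_ratio(alpha, r)
    c <- .cosh_ratio(alpha, r)
    P[!small] <- 1 - s / r
    U[!small] <- (alpha * r * c - s) / r^2
  }
  if (any(small)) {
    r <- rbar[small]
    sa <- if (alpha < 700) sinh(alpha) else Inf
    P[small] <- 1 - alpha * (1 + (alpha * r)^2 / 6) / sa
    U[small] <- alpha^3 * r / (3 * sa)
  }
  list(P = P, U = U)
}

# Shell functions for the necrotic core problem, rn in (0, 1]:
# N1(a) = alpha*rn*cosh(a) + sinh(a),  N2(a) = alpha*rn*sinh(a) + cosh(a),
# evaluated as exp(a) * n1(a) with n1, n2 bounded.
.n1 <- function(alpha, rn, a) (alpha * rn * (1 + exp(-2 * a)) - expm1(-2 * a)) / 2
.n2 <- function(alpha, rn, a) (-alpha * rn * expm1(-2 * a) + 1 + exp(-2 * a)) / 2

.check_grid <- function(rbar_grid) {
  if (!is.numeric(rbar_grid) || length(rbar_grid) < 1L ||
      any(!is.finite(rbar_grid)) || any(rbar_grid < 0) || any(rbar_grid > 1))
    stop("rbar_grid must lie within [0, 1]", call. = FALSE)
  rbar_grid
}

.new_dimensionless_profile <- function(rbar, P, U, alpha, rn_bar) {
  structure(data.frame(rbar = rbar, P = P, U = U),
            alpha = alpha, rn_bar = rn_bar,
            class = c("ifp_dimensionless_profile", "data.frame"))
}

#' Closed-form pressure profile of a uniform isolated spherical tumor
#'
#' Dimensionless steady-state interstitial pressure
#' `P(rbar) = 1 - sinh(alpha*rbar) / (rbar*sinh(alpha))` and radial Darcy
#' velocity `U = -dP/drbar` for a uniformly vascularised sphere with a
#' symmetry condition at the center and the surrounding pressure imposed at
#' the rim. The removable singularity at the center is evaluated by its
#' limit, `P(0) = 1 - alpha/sinh(alpha)`.
#'
#' @param alpha dimensionless resistance ratio (> 0), see [alpha_parameter()].
#' @param rbar_grid dimensionless radii in \[0, 1\].
#' @return A data frame of class `ifp_dimensionless_profile` with columns
#'   `rbar`, `P`, `U` and attributes `alpha`, `rn_bar`.
#' @export
#' @examples
#' prof <- solve_isolated_uniform(10)
#' prof$P[1]            # center pressure, close to 1 for large alpha
solve_isolated_uniform <- function(alpha, rbar_grid = seq(0, 1, length.out = 201)) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("alpha must be a single number > 0", call. = FALSE)
  rbar <- .check_grid(rbar_grid)
  pu <- .uniform_PU(alpha, rbar)
  .new_dimensionless_profile(rbar, pu$P, pu$U, alpha, 0)
}

#' Closed-form profile of an isolated tumor with a necrotic core
#'
#' Inside the sourceless necrotic core (`rbar < rn_bar`) the pressure obeys
#' the spherical Laplace equation; the regular solution is a constant, so the
#' core carries no flow. In the viable shell the uniform-source equation
#' holds. Pressure and flux are continuous at the core boundary and the rim
#' is held at the surrounding pressure. `rn_bar = 0` reduces exactly to
#' [solve_isolated_uniform()]; `rn_bar = 1` (fully necrotic, avascular tumor)
#' gives identically zero pressure.
#'
#' @inheritParams solve_isolated_uniform
#' @param rn_bar dimensionless necrotic radius in \[0, 1\].
#' @return A data frame of class `ifp_dimensionless_profile`.
#' @export
solve_necrotic <- function(alpha, rn_bar,
                           rbar_grid = seq(0, 1, length.out = 201)) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("alpha must be a single number > 0", call. = FALSE)
  if (!is.numeric(rn_bar) || length(rn_bar) != 1L || !is.finite(rn_bar) ||
      rn_bar < 0 || rn_bar > 1)
    stop("rn_bar must lie within [0, 1]", call. = FALSE)
  rbar <- .check_grid(rbar_grid)
  if (rn_bar < 1e-12) {
    out <- solve_isolated_uniform(alpha, rbar)
    attr(out, "rn_bar") <- rn_bar
    return(out)
  }
  s1 <- 1 - rn_bar
  a1 <- alpha * s1
  P <- U <- numeric(length(rbar))
  core <- rbar <= rn_bar
  # shell: P = 1 - N1(alpha*(r-rn)) / (r * N1(alpha*(1-rn)))
  if (any(!core)) {
    r <- rbar[!core]
    a <- alpha * (r - rn_bar)
    scale <- exp(a - a1)                      # e^a / e^a1, a <= a1
    den <- .n1(alpha, rn_bar, a1)
    P[!core] <- 1 - scale * .n1(alpha, rn_bar, a) / (r * den)
    U[!core] <- scale * (alpha * r * .n2(alpha, rn_bar, a) -
                           .n1(alpha, rn_bar, a)) / (r^2 * den)
  }
  # core: constant pressure, no flow
  if (any(core)) {
    P[core] <- 1 - exp(-a1) * alpha / .n1(alpha, rn_bar, a1)
    U[core] <- 0
  }
  .new_dimensionless_profile(rbar, P, U, alpha, rn_bar)
}

#' Dimensionless center pressure of a (possibly necrotic) tumor
#'
#' `P(0)` of [solve_necrotic()] in closed form:
#' `1 - alpha / (alpha*rn*cosh(alpha*(1-rn)) + sinh(alpha*(1-rn)))`.
#' Strictly increasing in `alpha`, non-increasing in `rn_bar`, zero for a
#' fully necrotic tumor, and tending to 1 (the effective pressure) as
#' `alpha` grows.
#'
#' @param alpha dimensionless resistance ratio (> 0); vectorised.
#' @param rn_bar dimensionless necrotic radius in \[0, 1\]; vectorised.
#' @return Dimensionless center pressure(s).
#' @export
center_pressure <- function(alpha, rn_bar = 0) {
  if (any(!is.finite(alpha)) || any(alpha <= 0))
    stop("alpha must be > 0", call. = FALSE)
  if (any(!is.finite(rn_bar)) || any(rn_bar < 0) || any(rn_bar > 1))
    stop("rn_bar must lie within [0, 1]", call. = FALSE)
  n <- max(length(alpha), length(rn_bar))
  alpha <- rep_len(alpha, n); rn <- rep_len(rn_bar, n)
  a1 <- alpha * (1 - rn)
  # alpha / N1(a1) = exp(-a1) * alpha / n1(a1); fully necrotic: n1 = alpha*rn
  1 - exp(-a1) * alpha / .n1(alpha, rn, a1)
}

#' Dimensionless outward fluid velocity at the tumor rim
#'
#' `U(1) = alpha*coth(alpha) - 1` for the uniform isolated sphere. The
#' dimensional rim speed is `K*(p_e - p_surr)/R * U(1)`.
#'
#' @param alpha dimensionless resistance ratio (> 0); vectorised.
#' @return Dimensionless rim velocity.
#' @export
rim_velocity_dimensionless <- function(alpha) {
  if (any(!is.finite(alpha)) || any(alpha <= 0))
    stop("alpha must be > 0", call. = FALSE)
  # coth(a) = (1 + exp(-2a)) / (1 - exp(-2a))
  alpha * (1 + exp(-2 * alpha)) / (-expm1(-2 * alpha)) - 1
}

#' Dimensional radial profile of an isolated (possibly necrotic) tumor
#'
#' Convenience wrapper around [solve_necrotic()] that restores physical
#' units and appends the Starling filtration rate. Filtration is zero inside
#' the necrotic core, where no functional vasculature remains.
#'
#' @param params tumor [tissue_parameters()].
#' @param R tumor radius, cm.
#' @param Rn necrotic-core radius, cm (`0 <= Rn <= R`).
#' @param p_surr surrounding pressure imposed at the rim, mmHg.
#' @param n number of radial sample points.
#' @return A data frame of class `ifp_profile` with columns `rbar`, `r_cm`,
#'   `P`, `p_mmHg`, `U`, `u_cm_per_s`, `u_um_per_s`, `phiB_per_s`.
#' @export
#' @examples
#' prof <- radial_profile(baseline_tissue_parameters("tumor"), R = 0.5)
#' max(prof$p_mmHg)
radial_profile <- function(params, R, Rn = 0, p_surr = 0, n = 401) {
  stopifnot(inherits(params, "tissue_parameters"))
  if (!is.numeric(R) || length(R) != 1L || R <= 0) stop("R must be > 0", call. = FALSE)
  if (!is.numeric(Rn) || length(Rn) != 1L || Rn < 0 || Rn > R)
    stop("Rn must lie within [0, R]", call. = FALSE)
  alpha <- alpha_parameter(params, R)
  p_e <- effective_pressure(params)
  rbar <- seq(0, 1, length.out = n)
  prof <- solve_necrotic(alpha, Rn / R, rbar)
  dp <- p_e - p_surr
  p <- p_surr + dp * prof$P
  u <- params$K * dp / R * prof$U
  phiB <- params$Lp * params$SV * (p_e - p)
  phiB[rbar < Rn / R - 1e-15] <- 0
  structure(data.frame(rbar = rbar, r_cm = rbar * R, P = prof$P, p_mmHg = p,
                       U = prof$U, u_cm_per_s = u, u_um_per_s = u * 1e4,
                       phiB_per_s = phiB),
            alpha = alpha, p_e = p_e, p_surr = p_surr, R = R, Rn = Rn,
            class = c("ifp_profile", "data.frame"))
}

#' Closed-form solution for a tumor embedded in normal tissue
#'
#' Two-region spherically symmetric solution: a uniformly vascularised tumor
#' of radius `R` surrounded by a normal-tissue shell extending to `R_out`,
#' where the far-field pressure `p_far` is imposed. Pressure and Darcy flux
#' (`K * dp/dr`) are continuous at the tumor boundary. Each region solves
#' the same source/sink equation with its own parameters; a region with zero
#' total filtration coefficient (no vasculature and no lymphatics) reduces
#' to the Laplace equation and is handled with its own solution basis.
#'
#' @param tumor,normal [tissue_parameters()] for the two regions.
#' @param R tumor radius, cm.
#' @param R_out outer radius of the normal-tissue shell, cm (`> R`).
#' @param p_far pressure imposed at `R_out`, mmHg.
#' @param n number of radial sample points.
#' @return A data frame of class `ifp_profile` with columns `r_cm`,
#'   `p_mmHg`, `u_cm_per_s`, `u_um_per_s`, `phiB_per_s`, `region`, plus
#'   attributes (`alpha` of the tumor region, `p_e` values, interface data).
#' @export
#' @examples
#' p <- solve_embedded(baseline_tissue_parameters("tumor"),
#'                     baseline_tissue_parameters("normal"),
#'                     R = 1.4, R_out = 4.2, p_far = 0)
#' p$p_mmHg[1]   # center pressure, near the tumor effective pressure
solve_embedded <- function(tumor, normal, R, R_out, p_far = 0, n = 601) {
  stopifnot(inherits(tumor, "tissue_parameters"),
            inherits(normal, "tissue_parameters"))
  if (!(is.numeric(R) && is.numeric(R_out) && R > 0 && R_out > R))
    stop("need 0 < R < R_out", call. = FALSE)

  lam_t <- filtration_rate_coefficient(tumor)
  lam_n <- filtration_rate_coefficient(normal)
  off_t <- if (lam_t > 0) steady_state_pressure(tumor) else 0
  off_n <- if (lam_n > 0) steady_state_pressure(normal) else 0
  at <- lam_t * R

  # tumor basis t1 (regular at the center, normalised to 1 at R) and its
  # radial derivative; Laplace limit: constant basis
  if (lam_t > 0) {
    t1 <- function(r) {
      pu <- .uniform_PU(at, r / R)
      1 - pu$P
    }
    # d/dr of sinh(lam*r)/(r*sinh(lam*R))*R: equals +U/R of the uniform
    # dimensionless solution (U = -dP/drbar and P = 1 - basis)
    t1p <- function(r) .uniform_PU(at, r / R)$U / R
  } else {
    t1 <- function(r) rep(1, length(r)); t1p <- function(r) rep(0, length(r))
  }
  # normal basis: decaying from R and from R_out (bounded on [R, R_out]);
  # Laplace limit: {1, R_out/r}
  if (lam_n > 0) {
    n1 <- function(r) (R / r) * exp(-lam_n * (r - R))
    n1p <- function(r) -R * exp(-lam_n * (r - R)) * (lam_n * r + 1) / r^2
    n2 <- function(r) (R_out / r) * exp(lam_n * (r - R_out))
    n2p <- function(r) R_out * exp(lam_n * (r - R_out)) * (lam_n * r - 1) / r^2
  } else {
    n1 <- function(r) rep(1, length(r)); n1p <- function(r) rep(0, length(r))
    n2 <- function(r) R_out / r;         n2p <- function(r) -R_out / r^2
  }

  M <- rbind(c(t1(R),              -n1(R),              -n2(R)),
             c(tumor$K * t1p(R),   -normal$K * n1p(R),  -normal$K * n2p(R)),
             c(0,                   n1(R_out),           n2(R_out)))
  rhs <- c(off_n - off_t, 0, p_far - off_n)
  coef <- tryCatch(solve(M, rhs),
                   error = function(e) stop("degenerate parameters: interface ",
                                            "system is singular", call. = FALSE))
  A <- coef[1]; B <- coef[2]; C <- coef[3]

  n_t <- max(3L, round(n * R / R_out))
  r_t <- seq(0, R, length.out = n_t)
  r_n <- seq(R, R_out, length.out = max(3L, n - n_t))
  p_t <- off_t + A * t1(r_t)
  u_t <- -tumor$K * A * t1p(r_t)
  p_n <- off_n + B * n1(r_n) + C * n2(r_n)
  u_n <- -normal$K * (B * n1p(r_n) + C * n2p(r_n))
  region <- c(rep("tumor", length(r_t)), rep("normal", length(r_n)))

  r <- c(r_t, r_n); p <- c(p_t, p_n); u <- c(u_t, u_n)
  phiB <- ifelse(region == "tumor",
                 tumor$Lp * tumor$SV * (effective_pressure(tumor) - p),
                 normal$Lp * normal$SV * (effective_pressure(normal) - p))
  # dimensionless view on the tumor scale (rbar spans [0, R_out/R])
  p_e_t <- effective_pressure(tumor)
  dp <- p_e_t - p_far
  P <- if (abs(dp) > 0) (p - p_far) / dp else rep(NA_real_, length(p))
  U <- if (abs(dp) > 0) u * R / (tumor$K * dp) else rep(NA_real_, length(p))
  structure(data.frame(rbar = r / R, r_cm = r, P = P, p_mmHg = p, U = U,
                       u_cm_per_s = u, u_um_per_s = u * 1e4,
                       phiB_per_s = phiB,
                       region = region, stringsAsFactors = FALSE),
            alpha = at, p_e_tumor = effective_pressure(tumor),
            p_e_normal = effective_pressure(normal), p_far = p_far,
            R = R, R_out = R_out, constants = coef,
            class = c("ifp_profile", "data.frame"))
}
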