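# Headline analyses: does the center interstitial pressure reach the
# effective pressure, and at which tumor / necrotic radii does that change?
# "Reaches effective pressure" is operationalised as dimensionless center
# pressure P(0) >= 1 - eps, with eps = 0.01 by default (1 percent of
# p_e - p_surr); every report states the eps used.

#' Critical tumor radius
#'
#' The smallest tumor radius whose center interstitial pressure comes within
#' `eps` of the effective pressure: the root of
#' `P(0) = 1 - alpha/sinh(alpha) = 1 - eps` in `R`, where
#' `alpha = R * sqrt(Lp*SV/K)`. `P(0)` is strictly increasing in `alpha`
#' (hence in `R`), so the root is found by bisection to relative precision
#' `1e-6`; a dense scan of the closed form serves as a fallback oracle in
#' the test-suite.
#'
#' @param params tumor [tissue_parameters()] (lymph-free).
#' @param eps tolerance defining "reaches effective pressure", in (0, 0.5).
#' @param R_range search interval in cm.
#' @return Critical radius in cm, with attributes `alpha_crit` and `eps`.
#'   If the range does not bracket the threshold, an error reports the
#'   attained `P(0)` bounds.
#' @export
#' @examples
#' critical_tumor_radius(baseline_tissue_parameters("tumor"))
critical_tumor_radius <- function(params, eps = 0.01, R_range = c(1e-4, 10)) {
  stopifnot(inherits(params, "tissue_parameters"))
  if (!(eps > 0 && eps < 0.5)) stop("eps must lie in (0, 0.5)", call. = FALSE)
  if (params$lymph_coeff != 0)
    stop("critical_tumor_radius assumes lymph-free tumor tissue", call. = FALSE)
  lam <- filtration_rate_coefficient(params)
  if (lam <= 0) stop("tumor has no vascular source (Lp*SV = 0)", call. = FALSE)
  target <- 1 - eps
  f <- function(R) center_pressure(lam * R) - target
  lo <- R_range[1]; hi <- R_range[2]
  flo <- f(lo); fhi <- f(hi)
  if (flo > 0 || fhi < 0)
    stop(sprintf(paste0("R_range does not bracket the critical radius: ",
                        "P(0) in [%.6g, %.6g] over the range"),
                 target + flo, target + fhi), call. = FALSE)
  while ((hi - lo) / hi > 1e-6) {
    mid <- (lo + hi) / 2
    if (f(mid) >= 0) hi <- mid else lo <- mid
  }
  structure((lo + hi) / 2, alpha_crit = lam * (lo + hi) / 2, eps = eps)
}

#' Critical necrotic radius
#'
#' The largest necrotic-core radius `Rn` in `[0, R]` at which the center
#' pressure still equals its non-necrotic maximum to within `eps`
#' (relative): `P(0; Rn) >= (1 - eps) * P(0; 0)`. The map `Rn -> P(0)` is
#' non-increasing, so bisection applies; for tumors above the critical tumor
#' radius the maximum itself equals the effective pressure within `eps`.
#'
#' @inheritParams critical_tumor_radius
#' @param R tumor radius, cm.
#' @return Critical necrotic radius in cm, with attributes `eps`,
#'   `P0_max` (center pressure at `Rn = 0`) and `rn_bar_crit`.
#' @export
critical_necrotic_radius <- function(params, R, eps = 0.01) {
  stopifnot(inherits(params, "tissue_parameters"))
  if (!(eps > 0 && eps < 0.5)) stop("eps must lie in (0, 0.5)", call. = FALSE)
  if (!(is.numeric(R) && R > 0)) stop("R must be > 0", call. = FALSE)
  alpha <- alpha_parameter(params, R)
  P0max <- center_pressure(alpha, 0)
  target <- (1 - eps) * P0max
  f <- function(rn) center_pressure(alpha, rn) - target
  if (f(1) >= 0) return(structure(R, eps = eps, P0_max = P0max, rn_bar_crit = 1))
  lo <- 0; hi <- 1
  while (hi - lo > 1e-9) {
    mid <- (lo + hi) / 2
    if (f(mid) >= 0) lo <- mid else hi <- mid
  }
  rn <- (lo + hi) / 2
  structure(rn * R, eps = eps, P0_max = P0max, rn_bar_crit = rn)
}

#' Sweep tumor radii
#'
#' Center pressure, rim velocity and the reached-effective-pressure flag for
#' a list of tumor radii at a fixed dimensionless necrotic radius. The
#' default path evaluates the closed-form solution; `path = "fvm"` runs the
#' radial finite-volume solver instead (the two agree to discretisation
#' error and are cross-checked in the test-suite).
#'
#' @param params tumor [tissue_parameters()].
#' @param radii tumor radii in cm.
#' @param rn_bar dimensionless necrotic radius applied to every tumor.
#' @param eps "reaches effective pressure" tolerance.
#' @param p_surr surrounding pressure, mmHg.
#' @param path `"analytic"` or `"fvm"`.
#' @param N cells for the finite-volume path.
#' @return A data frame of class `ifp_sweep` with columns `R_cm`, `Rn_cm`,
#'   `rn_bar`, `alpha`, `P_center`, `p_center_mmHg`, `u_rim_um_per_s`,
#'   `reached_pe`; attribute `eps`.
#' @export
#' @examples
#' radius_sweep(baseline_tissue_parameters("tumor"), c(0.1, 0.25, 0.5, 1))
radius_sweep <- function(params, radii, rn_bar = 0, eps = 0.01, p_surr = 0,
                         path = c("analytic", "fvm"), N = 2000) {
  stopifnot(inherits(params, "tissue_parameters"))
  if (any(radii <= 0)) stop("radii must be > 0", call. = FALSE)
  if (!(rn_bar >= 0 && rn_bar <= 1)) stop("rn_bar must lie in [0, 1]", call. = FALSE)
  path <- match.arg(path)
  p_e <- effective_pressure(params)
  out <- lapply(radii, function(R) {
    alpha <- alpha_parameter(params, R)
    if (path == "analytic") {
      P0 <- center_pressure(alpha, rn_bar)
      Urim <- if (rn_bar < 1) {
        if (rn_bar == 0) rim_velocity_dimensionless(alpha)
        else utils::tail(solve_necrotic(alpha, rn_bar, c(0, 1))$U, 1)
      } else 0
      u_rim <- params$K * (p_e - p_surr) / R * Urim
      P0c <- P0
    } else {
      g <- build_radial_grid(R = R, Rn = rn_bar * R, N = N)
      sol <- solve_radial(g, list(tumor = params), p_out = p_surr)
      dp <- p_e - p_surr
      P0c <- (sol$report$center_pressure - p_surr) / dp
      u_rim <- sol$report$rim_velocity_cm_per_s
    }
    data.frame(R_cm = R, Rn_cm = rn_bar * R, rn_bar = rn_bar, alpha = alpha,
               P_center = P0c,
               p_center_mmHg = p_surr + (p_e - p_surr) * P0c,
               u_rim_um_per_s = u_rim * 1e4,
               reached_pe = P0c >= 1 - eps)
  })
  structure(do.call(rbind, out), eps = eps, p_e = p_e, p_surr = p_surr,
            path = path, class = c("ifp_sweep", "data.frame"))
}

#' Sweep necrotic radii at fixed tumor radius
#'
#' @inheritParams radius_sweep
#' @param R tumor radius, cm.
#' @param rn_bars dimensionless necrotic radii in \[0, 1\].
#' @return A data frame of class `ifp_sweep` (same schema as
#'   [radius_sweep()]).
#' @export
necrotic_sweep <- function(params, R, rn_bars = seq(0, 1, by = 0.02),
                           eps = 0.01, p_surr = 0) {
  stopifnot(inherits(params, "tissue_parameters"))
  if (!(is.numeric(R) && R > 0)) stop("R must be > 0", call. = FALSE)
  alpha <- alpha_parameter(params, R)
  p_e <- effective_pressure(params)
  P0 <- center_pressure(alpha, rn_bars)
  Urim <- vapply(rn_bars, function(rn) {
    if (rn >= 1) 0 else utils::tail(solve_necrotic(alpha, rn, c(0, 1))$U, 1)
  }, numeric(1))
  structure(data.frame(R_cm = R, Rn_cm = rn_bars * R, rn_bar = rn_bars,
                       alpha = alpha, P_center = P0,
                       p_center_mmHg = p_surr + (p_e - p_surr) * P0,
                       u_rim_um_per_s = params$K * (p_e - p_surr) / R * Urim * 1e4,
                       reached_pe = P0 >= 1 - eps),
            eps = eps, p_e = p_e, p_surr = p_surr, path = "analytic",
            class = c("ifp_sweep", "data.frame"))
}

#' Starling filtration profile
#'
#' Per-point volumetric filtration rate from the vasculature,
#' `phi_B(r) = Lp*SV*(p_e - p(r))`. Filtration peaks at the rim of an
#' isolated uniform tumor and is near zero in a high-pressure core; it is
#' identically zero in necrotic tissue.
#'
#' @param profile an `ifp_profile` data frame (from [radial_profile()],
#'   [as_profile()] or [solve_embedded()]) containing `p_mmHg`.
#' @param params [tissue_parameters()] of the (viable) tissue.
#' @return Numeric vector of filtration rates, s^-1.
#' @export
filtration_profile <- function(profile, params) {
  stopifnot(is.data.frame(profile), "p_mmHg" %in% names(profile),
            inherits(params, "tissue_parameters"))
  phi <- params$Lp * params$SV * (effective_pressure(params) - profile$p_mmHg)
  Rn <- attr(profile, "Rn")
  if (!is.null(Rn) && Rn > 0 && "r_cm" %in% names(profile))
    phi[profile$r_cm < Rn - 1e-15] <- 0
  phi
}
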