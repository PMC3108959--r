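# Conservative cell-centered finite-volume discretisation of
#   -(1/r^2) d/dr ( r^2 K dp/dr ) = phi_B - phi_L
# on a 1-D spherically symmetric grid with piecewise-constant tissue regions
# (necrotic core / viable tumor / normal shell). Face fluxes use exact
# spherical face areas 4*pi*r_f^2 and harmonic-mean conductivities, so the
# scheme telescopes: integrated net source equals the boundary outflux to
# linear-solver precision.

#' Build a 1-D spherically symmetric finite-volume grid
#'
#' Faces run from the center to `R_out`, snapped so that the necrotic radius
#' `Rn` and the tumor radius `R` coincide exactly with cell faces: region
#' boundaries are then conservative flux interfaces. Spacing is uniform
#' within each region (cell counts allocated proportionally to region
#' widths).
#'
#' @param R tumor radius, cm.
#' @param Rn necrotic-core radius, cm (`0 <= Rn <= R`).
#' @param R_out outer domain radius, cm (`>= R`); equals `R` for an isolated
#'   tumor, larger when a normal-tissue shell is included.
#' @param N total number of cells (`>= 3`, and at least one per region).
#' @return An object of class `radial_grid`: list with `faces` (length
#'   `N + 1`), `centers`, `N` and `region` (per-cell label in
#'   `"necrotic"`, `"tumor"`, `"normal"`).
#' @export
#' @examples
#' g <- build_radial_grid(R = 1, Rn = 0.5, N = 10)
#' g$faces  # face exactly at 0.5
build_radial_grid <- function(R, Rn = 0, R_out = R, N = 200) {
  if (!(is.numeric(R) && R > 0 && Rn >= 0 && Rn <= R && R_out >= R))
    stop("need 0 <= Rn <= R <= R_out", call. = FALSE)
  if (!is.numeric(N) || N < 3) stop("N must be >= 3", call. = FALSE)
  N <- as.integer(N)
  widths <- c(necrotic = Rn, tumor = R - Rn, normal = R_out - R)
  active <- widths > 0
  if (!any(active)) stop("degenerate geometry: zero total radius", call. = FALSE)
  if (sum(active) > N)
    stop("N too small to resolve all tissue regions", call. = FALSE)
  # proportional allocation, at least one cell per nonempty region
  n_cells <- integer(3)
  n_cells[active] <- pmax(1L, round(N * widths[active] / sum(widths)))
  # adjust to total N (largest region absorbs the correction)
  k <- which.max(widths)
  n_cells[k] <- n_cells[k] + (N - sum(n_cells))
  if (any(n_cells[active] < 1L))
    stop("N too small to resolve all tissue regions", call. = FALSE)
  bounds <- c(0, Rn, R, R_out)
  faces <- 0
  region <- character(0)
  labs <- c("necrotic", "tumor", "normal")
  for (i in 1:3) {
    if (!active[i]) next
    f <- seq(bounds[i], bounds[i + 1], length.out = n_cells[i] + 1L)
    faces <- c(faces, f[-1])
    region <- c(region, rep(labs[i], n_cells[i]))
  }
  faces <- as.numeric(faces)
  structure(list(faces = faces, centers = (faces[-1] + faces[-length(faces)]) / 2,
                 N = length(region), region = region,
                 R = R, Rn = Rn, R_out = R_out),
            class = "radial_grid")
}

#' @export
print.radial_grid <- function(x, ...) {
  cat(sprintf("Radial FV grid: %d cells on [0, %.4g] cm (R = %.4g, Rn = %.4g)\n",
              x$N, x$R_out, x$R, x$Rn))
  cat("  cells per region:",
      paste(names(table(x$region)), table(x$region), collapse = ", "), "\n")
  invisible(x)
}

# per-cell source coefficients: phi_B - phi_L = a - b*p with
# a = Lp*SV*p_e + lymph*pL, b = Lp*SV + lymph
.source_coeffs <- function(grid, params_by_region) {
  a <- b <- K <- numeric(grid$N)
  for (lab in unique(grid$region)) {
    pr <- params_by_region[[lab]]
    if (is.null(pr))
      stop("params_by_region is missing region '", lab, "'", call. = FALSE)
    stopifnot(inherits(pr, "tissue_parameters"))
    idx <- grid$region == lab
    fb <- pr$Lp * pr$SV
    a[idx] <- fb * effective_pressure(pr) + pr$lymph_coeff * pr$pL
    b[idx] <- fb + pr$lymph_coeff
    K[idx] <- pr$K
  }
  list(a = a, b = b, K = K)
}

# tridiagonal system (lower, diag, upper, rhs) for the radial FV scheme with
# a Dirichlet value at the outer face and zero flux at the center.
# The outer-face flux uses a quadratic (second-order one-sided) gradient
# through p_out, p_N, p_{N-1} when the last two cells share region and
# spacing; otherwise the half-cell two-point gradient.
.assemble_radial <- function(grid, src, p_out) {
  N <- grid$N
  f <- grid$faces
  rc <- grid$centers
  area <- 4 * pi * f^2
  vol <- 4 * pi / 3 * diff(f^3)
  # interior face conductances g_i couple cells i and i+1 (i = 1..N-1)
  dK <- src$K
  g_int <- if (N > 1) {
    Kf <- 2 * dK[-N] * dK[-1] / (dK[-N] + dK[-1])     # harmonic mean
    Kf * area[2:N] / (rc[-1] - rc[-N])
  } else numeric(0)
  dia <- src$b * vol
  dia[1:(N - 1)] <- dia[1:(N - 1)] + g_int
  if (N > 1) dia[2:N] <- dia[2:N] + g_int
  rhs <- src$a * vol
  lower <- -g_int
  h_last <- f[N + 1] - f[N]
  quad <- N > 1 && grid$region[N] == grid$region[N - 1] &&
    abs((f[N] - f[N - 1]) - h_last) < 1e-12 * h_last
  if (quad) {
    # F_out = K*A/(3h) * (9 p_N - p_{N-1} - 8 p_out)
    gq <- dK[N] * area[N + 1] / (3 * h_last)
    dia[N] <- dia[N] + 9 * gq
    lower[N - 1] <- lower[N - 1] - gq
    rhs[N] <- rhs[N] + 8 * gq * p_out
    bnd <- list(kind = "quad", gq = gq)
  } else {
    g_out <- dK[N] * area[N + 1] / (f[N + 1] - rc[N])
    dia[N] <- dia[N] + g_out
    rhs[N] <- rhs[N] + g_out * p_out
    bnd <- list(kind = "half", g_out = g_out)
  }
  list(lower = lower, diag = dia, upper = -g_int, rhs = rhs,
       vol = vol, bnd = bnd, area = area)
}

# outward boundary flux (cm^3/s) and rim velocity (cm/s) consistent with
# the assembled boundary treatment
.boundary_flux <- function(grid, src, sys, p, p_out) {
  N <- grid$N
  if (sys$bnd$kind == "quad") {
    flux <- sys$bnd$gq * (9 * p[N] - p[N - 1] - 8 * p_out)
  } else {
    flux <- sys$bnd$g_out * (p[N] - p_out)
  }
  list(flux = flux, u = flux / sys$area[N + 1])
}

# Thomas algorithm for a tridiagonal system
.thomas <- function(lower, dia, upper, rhs) {
  n <- length(dia)
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- if (n > 1) upper[1] / dia[1] else 0
  dp[1] <- rhs[1] / dia[1]
  if (n > 1) {
    for (i in 2:n) {
      m <- dia[i] - lower[i - 1] * cp[i - 1]
      if (i < n) cp[i] <- upper[i] / m
      dp[i] <- (rhs[i] - lower[i - 1] * dp[i - 1]) / m
    }
  }
  x <- numeric(n)
  x[n] <- dp[n]
  if (n > 1) for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

# residual of the tridiagonal system
.tri_residual <- function(lower, dia, upper, rhs, x) {
  n <- length(x)
  Ax <- dia * x
  if (n > 1) {
    Ax[1:(n - 1)] <- Ax[1:(n - 1)] + upper * x[2:n]
    Ax[2:n] <- Ax[2:n] + lower * x[1:(n - 1)]
  }
  rhs - Ax
}

# red-black SOR sweeps on a tridiagonal system (odd/even cells form an exact
# two-colouring); relaxation < 1 is under-relaxation, > 1 over-relaxation
.sor_tridiag <- function(lower, dia, upper, rhs, relaxation, tol, max_iter) {
  n <- length(dia)
  x <- numeric(n)
  r0 <- sqrt(sum(rhs^2))
  if (r0 == 0) return(list(x = x, iterations = 0L, rel_residual = 0, converged = TRUE))
  odd <- seq(1, n, by = 2); even <- seq(2, n, by = 2)
  res_hist <- numeric(0)
  for (it in seq_len(max_iter)) {
    for (color in list(odd, even)) {
      r <- .tri_residual(lower, dia, upper, rhs, x)
      x[color] <- x[color] + relaxation * r[color] / dia[color]
    }
    rel <- sqrt(sum(.tri_residual(lower, dia, upper, rhs, x)^2)) / r0
    res_hist <- c(res_hist, rel)
    if (rel <= tol)
      return(list(x = x, iterations = it, rel_residual = rel, converged = TRUE,
                  residual_history = res_hist))
  }
  list(x = x, iterations = max_iter, rel_residual = rel, converged = FALSE,
       residual_history = res_hist)
}

#' Solve the radial finite-volume pressure system
#'
#' Assembles and solves the conservative cell-centered discretisation of the
#' steady Darcy/Starling equation on a [build_radial_grid()]. The affine
#' source `phi_B - phi_L` is treated implicitly (it is linear in pressure),
#' the center face carries zero flux by symmetry, and the outer face holds a
#' Dirichlet pressure: the surrounding pressure for an isolated tumor, or
#' the far-field pressure when the grid includes a normal-tissue shell
#' (embedded case).
#'
#' @param grid a [build_radial_grid()] object.
#' @param params_by_region named list of [tissue_parameters()], one entry per
#'   region label present in the grid (`necrotic`, `tumor`, `normal`). The
#'   necrotic entry defaults to [necrotic_parameters()] of the tumor entry.
#' @param p_out Dirichlet pressure at the outer face, mmHg.
#' @param method `"direct"` (tridiagonal elimination, default) or `"sor"`
#'   (red-black successive over-relaxation sweeps).
#' @param tol relative residual reduction for `"sor"` (default `1e-6`, i.e.
#'   six orders of magnitude).
#' @param relaxation SOR relaxation factor (default 0.75, under-relaxed).
#' @param max_iter iteration cap for `"sor"`.
#' @return A list of class `ifp_radial_solution`: `grid`, `p` (cell-centered
#'   pressures, mmHg), and `report` (class `ifp_solve_report`) with
#'   `iterations`, `final_residual`, `conservation_gap`, `alpha`, `p_e`,
#'   `center_pressure`, `rim_velocity` and related scalars.
#' @export
#' @examples
#' tum <- baseline_tissue_parameters("tumor")
#' g <- build_radial_grid(R = 1, N = 500)
#' sol <- solve_radial(g, list(tumor = tum), p_out = 0)
#' sol$report$center_pressure
solve_radial <- function(grid, params_by_region, p_out = 0,
                         method = c("direct", "sor"), tol = 1e-6,
                         relaxation = 0.75, max_iter = 100000L) {
  stopifnot(inherits(grid, "radial_grid"))
  method <- match.arg(method)
  if (is.null(params_by_region$necrotic) && "necrotic" %in% grid$region) {
    if (is.null(params_by_region$tumor))
      stop("need tumor parameters to derive the necrotic region", call. = FALSE)
    params_by_region$necrotic <- necrotic_parameters(params_by_region$tumor)
  }
  src <- .source_coeffs(grid, params_by_region)
  sys <- .assemble_radial(grid, src, p_out)

  if (method == "direct") {
    p <- .thomas(sys$lower, sys$diag, sys$upper, sys$rhs)
    r <- .tri_residual(sys$lower, sys$diag, sys$upper, sys$rhs, p)
    r0 <- sqrt(sum(sys$rhs^2))
    rel <- if (r0 > 0) sqrt(sum(r^2)) / r0 else 0
    iters <- 1L; converged <- TRUE; hist <- rel
  } else {
    it <- .sor_tridiag(sys$lower, sys$diag, sys$upper, sys$rhs,
                       relaxation, tol, max_iter)
    if (!it$converged)
      warning(sprintf("SOR did not reach tol %.1e in %d iterations (residual %.2e)",
                      tol, it$iterations, it$rel_residual))
    p <- it$x; rel <- it$rel_residual; iters <- it$iterations
    converged <- it$converged; hist <- it$residual_history
  }

  # conservation: integrated net source vs outer boundary outflux
  net_source <- sum((src$a - src$b * p) * sys$vol)
  bf <- .boundary_flux(grid, src, sys, p, p_out)
  outflux <- bf$flux
  gap <- abs(net_source - outflux) / max(abs(outflux), abs(net_source), 1e-300)

  tum <- params_by_region$tumor
  alpha <- if (!is.null(tum)) alpha_parameter(tum, grid$R) else NA_real_
  p_e <- if (!is.null(tum)) effective_pressure(tum) else NA_real_
  u_rim <- bf$u
  report <- structure(list(
    method = method, iterations = iters, final_residual = rel,
    converged = converged, residual_history = hist,
    conservation_gap = gap, net_source_cm3_per_s = net_source,
    boundary_outflux_cm3_per_s = outflux,
    alpha = alpha, p_e = p_e, p_out = p_out,
    center_pressure = p[1], rim_velocity_cm_per_s = u_rim,
    rim_velocity_um_per_s = u_rim * 1e4,
    N = grid$N), class = "ifp_solve_report")
  structure(list(grid = grid, p = p, src = src,
                 sys = sys[c("bnd", "area", "vol")], report = report),
            class = "ifp_radial_solution")
}

#' @export
print.ifp_solve_report <- function(x, ...) {
  cat(sprintf("FV solve (%s): %d iteration(s), relative residual %.2e%s\n",
              x$method, x$iterations, x$final_residual,
              if (isTRUE(x$converged)) "" else " [NOT CONVERGED]"))
  cat(sprintf("  conservation gap %.2e | alpha = %.4g | p_e = %.4g mmHg\n",
              x$conservation_gap, x$alpha, x$p_e))
  cat(sprintf("  center pressure %.4g mmHg | rim velocity %.4g um/s\n",
              x$center_pressure, x$rim_velocity_um_per_s))
  invisible(x)
}

#' Face-centered Darcy velocities from a radial solution
#'
#' `u = -K_face * (p_right - p_left) / dr` at each interior face (harmonic
#' mean `K`), zero at the center face by symmetry, and the one-sided
#' half-cell gradient to the Dirichlet value at the outer face.
#'
#' @param solution an `ifp_radial_solution` from [solve_radial()].
#' @return Data frame with `r_cm` (face radii), `u_cm_per_s`, `u_um_per_s`.
#' @export
darcy_velocity <- function(solution) {
  stopifnot(inherits(solution, "ifp_radial_solution"))
  g <- solution$grid; p <- solution$p; K <- solution$src$K
  N <- g$N
  u <- numeric(N + 1)
  if (N > 1) {
    Kf <- 2 * K[-N] * K[-1] / (K[-N] + K[-1])
    u[2:N] <- -Kf * (p[-1] - p[-N]) / (g$centers[-1] - g$centers[-N])
  }
  u[N + 1] <- .boundary_flux(g, solution$src, solution$sys, p,
                             solution$report$p_out)$u
  data.frame(r_cm = g$faces, u_cm_per_s = u, u_um_per_s = u * 1e4)
}

#' Dimensional profile data frame from a radial finite-volume solution
#'
#' Interpolates face velocities to cell centers and assembles the standard
#' profile schema used by the CSV export, mirroring [radial_profile()].
#'
#' @param solution an `ifp_radial_solution`.
#' @return A data frame of class `ifp_profile` with columns `rbar`, `r_cm`,
#'   `P`, `p_mmHg`, `U`, `u_cm_per_s`, `u_um_per_s`, `phiB_per_s`.
#' @export
as_profile <- function(solution) {
  stopifnot(inherits(solution, "ifp_radial_solution"))
  g <- solution$grid
  p <- solution$p
  rep <- solution$report
  vel <- darcy_velocity(solution)
  u_c <- (vel$u_cm_per_s[-1] + vel$u_cm_per_s[-(g$N + 1)]) / 2
  dp <- rep$p_e - rep$p_out
  P <- if (abs(dp) > 0) (p - rep$p_out) / dp else rep(NA_real_, g$N)
  U <- if (abs(dp) > 0) u_c * g$R / (solution$src$K * dp) else rep(NA_real_, g$N)
  # net volumetric source phi_B - phi_L; equals phi_B in lymph-free tissue
  phiB <- solution$src$a - solution$src$b * p
  structure(data.frame(rbar = g$centers / g$R, r_cm = g$centers, P = P,
                       p_mmHg = p, U = U, u_cm_per_s = u_c,
                       u_um_per_s = u_c * 1e4, phiB_per_s = phiB),
            alpha = rep$alpha, p_e = rep$p_e, p_surr = rep$p_out,
            R = g$R, Rn = g$Rn,
            class = c("ifp_profile", "data.frame"))
}
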