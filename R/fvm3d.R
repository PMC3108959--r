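# Voxel-based 3-D finite-volume solver for the steady Darcy/Starling
# equation on structured grids. Seven-point conservative stencil, face
# conductivities by harmonic mean, affine source per voxel by region.
# Dirichlet pressure is imposed on the outer box faces and at voxels labeled
# "exterior" (which lets a spherical outer boundary be carved out of the box).

.LABELS <- c(exterior = 0L, necrotic = 1L, tumor = 2L, normal = 3L)

#' Voxelize a spherical (possibly necrotic) tumor with a surrounding shell
#'
#' Deterministically labels a cubic voxel grid spanning
#' `[-R_out, R_out]^3` by voxel-center distance from the origin: necrotic
#' inside `Rn`, tumor inside `R`, normal inside `R_out`, exterior beyond
#' (exterior voxels are held at the boundary pressure by [solve_3d()], so
#' the Dirichlet surface is the sphere of radius `R_out` rather than the
#' box).
#'
#' @param R tumor radius, cm.
#' @param Rn necrotic radius, cm (`0 <= Rn <= R`).
#' @param R_out outer (Dirichlet) radius, cm (`>= R`).
#' @param n_per_axis voxels per axis (`>= 16`).
#' @return An object of class `voxel_geometry`: `labels` (integer
#'   `n^3` array, see `label_map`), `spacing` (cm), `origin` (cm),
#'   `n`, and the generating radii.
#' @export
#' @examples
#' g <- voxelize_sphere(R = 0.1, R_out = 0.2, n_per_axis = 32)
#' table(g$labels)
voxelize_sphere <- function(R, Rn = 0, R_out = R, n_per_axis = 64) {
  if (!(is.numeric(R) && R > 0 && Rn >= 0 && Rn <= R && R_out >= R))
    stop("need 0 <= Rn <= R <= R_out", call. = FALSE)
  if (n_per_axis < 16) stop("n_per_axis must be >= 16", call. = FALSE)
  n <- as.integer(n_per_axis)
  h <- 2 * R_out / n
  x <- -R_out + (seq_len(n) - 0.5) * h
  d2 <- outer(outer(x^2, x^2, `+`), x^2, `+`)
  d <- sqrt(d2)
  labels <- array(.LABELS[["normal"]], dim = c(n, n, n))
  labels[d >= R_out] <- .LABELS[["exterior"]]
  labels[d < R] <- .LABELS[["tumor"]]
  labels[d < Rn] <- .LABELS[["necrotic"]]
  if (!any(labels == .LABELS[["tumor"]]) && !any(labels == .LABELS[["necrotic"]]))
    stop("resolution too coarse: no voxel falls inside the tumor", call. = FALSE)
  structure(list(labels = labels, spacing = h, origin = -R_out, n = n,
                 R = R, Rn = Rn, R_out = R_out, label_map = .LABELS),
            class = "voxel_geometry")
}

#' @export
print.voxel_geometry <- function(x, ...) {
  tab <- table(factor(x$labels, levels = x$label_map,
                      labels = names(x$label_map)))
  cat(sprintf("Voxel geometry: %d^3 voxels, spacing %.4g cm\n", x$n, x$spacing))
  print(tab)
  invisible(x)
}

# voxel-center coordinates along one axis
.voxel_axis <- function(geom) geom$origin + (seq_len(geom$n) - 0.5) * geom$spacing

# voxel-center radii (array)
.voxel_radii <- function(geom) {
  x <- .voxel_axis(geom)
  sqrt(outer(outer(x^2, x^2, `+`), x^2, `+`))
}

# per-voxel K, a, b from region labels (exterior voxels get NA)
.voxel_coeffs <- function(geom, params_by_region) {
  if (is.null(params_by_region$necrotic) &&
      any(geom$labels == .LABELS[["necrotic"]])) {
    if (is.null(params_by_region$tumor))
      stop("need tumor parameters to derive the necrotic region", call. = FALSE)
    params_by_region$necrotic <- necrotic_parameters(params_by_region$tumor)
  }
  nv <- length(geom$labels)
  K <- a <- b <- rep(NA_real_, nv)
  for (lab in c("necrotic", "tumor", "normal")) {
    code <- .LABELS[[lab]]
    idx <- which(geom$labels == code)
    if (!length(idx)) next
    pr <- params_by_region[[lab]]
    if (is.null(pr))
      stop("params_by_region is missing region '", lab, "'", call. = FALSE)
    stopifnot(inherits(pr, "tissue_parameters"))
    fb <- pr$Lp * pr$SV
    K[idx] <- pr$K
    a[idx] <- fb * effective_pressure(pr) + pr$lymph_coeff * pr$pL
    b[idx] <- fb + pr$lymph_coeff
  }
  list(K = K, a = a, b = b)
}

# Jacobi-preconditioned conjugate gradients for a symmetric positive-definite
# sparse system
.pcg <- function(A, rhs, tol, max_iter) {
  m <- length(rhs)
  x <- numeric(m)
  r <- rhs
  r0 <- sqrt(sum(r^2))
  if (r0 == 0) return(list(x = x, iterations = 0L, rel_residual = 0,
                           converged = TRUE, residual_history = numeric(0)))
  d <- Matrix::diag(A)
  z <- r / d
  p <- z
  rz <- sum(r * z)
  hist <- numeric(0)
  for (it in seq_len(max_iter)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rel <- sqrt(sum(r^2)) / r0
    hist <- c(hist, rel)
    if (rel <= tol)
      return(list(x = x, iterations = it, rel_residual = rel, converged = TRUE,
                  residual_history = hist))
    z <- r / d
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  list(x = x, iterations = max_iter, rel_residual = rel, converged = FALSE,
       residual_history = hist)
}

# red-black SOR on a sparse system given a two-colouring of the unknowns
.sor_sparse <- function(A, rhs, color, relaxation, tol, max_iter) {
  m <- length(rhs)
  x <- numeric(m)
  r0 <- sqrt(sum(rhs^2))
  if (r0 == 0) return(list(x = x, iterations = 0L, rel_residual = 0,
                           converged = TRUE, residual_history = numeric(0)))
  d <- Matrix::diag(A)
  red <- which(color); black <- which(!color)
  hist <- numeric(0)
  for (it in seq_len(max_iter)) {
    r <- rhs - as.numeric(A %*% x)
    x[red] <- x[red] + relaxation * r[red] / d[red]
    r <- rhs - as.numeric(A %*% x)
    x[black] <- x[black] + relaxation * r[black] / d[black]
    rel <- sqrt(sum((rhs - as.numeric(A %*% x))^2)) / r0
    hist <- c(hist, rel)
    if (rel <= tol)
      return(list(x = x, iterations = it, rel_residual = rel, converged = TRUE,
                  residual_history = hist))
  }
  list(x = x, iterations = max_iter, rel_residual = rel, converged = FALSE,
       residual_history = hist)
}

#' Solve the 3-D voxel finite-volume pressure system
#'
#' Seven-point conservative finite-volume discretisation on a
#' [voxelize_sphere()] geometry (or any `voxel_geometry`). Face
#' conductivities are harmonic means of the adjacent voxel conductivities;
#' each voxel carries the affine Starling/lymphatic source of its region
#' (zero in necrotic voxels). The boundary pressure is imposed on the outer
#' box faces (half-voxel distance) and at exterior-labeled voxels. The
#' resulting symmetric positive-definite system is solved by
#' Jacobi-preconditioned conjugate gradients (default) or red-black SOR
#' sweeps (relaxation 0.75 by default), iterating until the residual has
#' dropped by six orders of magnitude (`tol = 1e-6`) or better.
#'
#' @param geom a `voxel_geometry`.
#' @param params_by_region named list of [tissue_parameters()] (entries
#'   `tumor`, `normal`, optionally `necrotic`; necrotic defaults to
#'   [necrotic_parameters()] of the tumor entry).
#' @param p_boundary Dirichlet pressure, mmHg.
#' @param method `"pcg"` or `"sor"`.
#' @param tol relative residual reduction target.
#' @param relaxation SOR relaxation factor.
#' @param max_iter iteration cap.
#' @return A list of class `ifp_voxel_solution`: `geom`, `p` (full
#'   `n^3` array, boundary pressure at exterior voxels), `coeffs`, and
#'   `report` (class `ifp_solve_report`).
#' @export
#' @examples
#' g <- voxelize_sphere(R = 0.1, R_out = 0.15, n_per_axis = 24)
#' sol <- solve_3d(g, list(tumor = baseline_tissue_parameters("tumor"),
#'                         normal = baseline_tissue_parameters("normal")))
#' sol$report$center_pressure
solve_3d <- function(geom, params_by_region, p_boundary = 0,
                     method = c("pcg", "sor"), tol = 1e-6,
                     relaxation = 0.75, max_iter = 10000L) {
  stopifnot(inherits(geom, "voxel_geometry"))
  method <- match.arg(method)
  n <- geom$n; h <- geom$spacing
  cf <- .voxel_coeffs(geom, params_by_region)
  unknown <- geom$labels != .LABELS[["exterior"]]
  m <- sum(unknown)
  if (m == 0) stop("geometry contains no interior voxels", call. = FALSE)
  id <- array(0L, dim = dim(geom$labels))
  id[unknown] <- seq_len(m)

  vol <- h^3
  dia <- cf$b[unknown] * vol            # source contribution (implicit)
  rhs <- cf$a[unknown] * vol
  Kv <- array(cf$K, dim = dim(geom$labels))

  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  dir_i <- integer(0); dir_g <- numeric(0)   # Dirichlet links for conservation

  slice <- function(arr, axis, drop_last) {
    idx <- if (drop_last) 1:(n - 1) else 2:n
    switch(axis, arr[idx, , , drop = FALSE], arr[, idx, , drop = FALSE],
           arr[, , idx, drop = FALSE])
  }
  for (axis in 1:3) {
    idL <- slice(id, axis, TRUE);  idR <- slice(id, axis, FALSE)
    KL  <- slice(Kv, axis, TRUE);  KR  <- slice(Kv, axis, FALSE)
    both <- idL > 0 & idR > 0
    if (any(both)) {
      g <- 2 * KL[both] * KR[both] / (KL[both] + KR[both]) * h
      i <- idL[both]; j <- idR[both]
      ii <- c(ii, i, j); jj <- c(jj, j, i); vv <- c(vv, -g, -g)
      dia[i] <- dia[i] + g; dia[j] <- dia[j] + g
    }
    # unknown voxel facing an exterior voxel: Dirichlet at neighbour center
    lex <- idL > 0 & idR == 0
    if (any(lex)) {
      g <- KL[lex] * h; i <- idL[lex]
      dia_add <- tapply(g, i, sum)
      tgt <- as.integer(names(dia_add))
      dia[tgt] <- dia[tgt] + as.numeric(dia_add)
      rhs[tgt] <- rhs[tgt] + as.numeric(dia_add) * p_boundary
      dir_i <- c(dir_i, i); dir_g <- c(dir_g, g)
    }
    rex <- idR > 0 & idL == 0
    if (any(rex)) {
      g <- KR[rex] * h; i <- idR[rex]
      dia_add <- tapply(g, i, sum)
      tgt <- as.integer(names(dia_add))
      dia[tgt] <- dia[tgt] + as.numeric(dia_add)
      rhs[tgt] <- rhs[tgt] + as.numeric(dia_add) * p_boundary
      dir_i <- c(dir_i, i); dir_g <- c(dir_g, g)
    }
    # box faces: Dirichlet at the face, half-voxel distance
    for (side in c(1L, n)) {
      face_id <- switch(axis, id[side, , ], id[, side, ], id[, , side])
      face_K <- switch(axis, Kv[side, , ], Kv[, side, ], Kv[, , side])
      sel <- face_id > 0
      if (any(sel)) {
        g <- 2 * face_K[sel] * h; i <- face_id[sel]
        dia[i] <- dia[i] + g
        rhs[i] <- rhs[i] + g * p_boundary
        dir_i <- c(dir_i, i); dir_g <- c(dir_g, g)
      }
    }
  }
  A <- Matrix::sparseMatrix(i = c(ii, seq_len(m)), j = c(jj, seq_len(m)),
                            x = c(vv, dia), dims = c(m, m))

  if (method == "pcg") {
    it <- .pcg(A, rhs, tol, max_iter)
  } else {
    ijk <- which(unknown, arr.ind = TRUE)
    color <- (rowSums(ijk) %% 2L) == 0L
    it <- .sor_sparse(A, rhs, color, relaxation, tol, max_iter)
  }
  if (!it$converged)
    warning(sprintf("3-D solve did not reach tol %.1e in %d iterations (residual %.2e)",
                    tol, it$iterations, it$rel_residual))

  p <- array(p_boundary, dim = dim(geom$labels))
  p[unknown] <- it$x

  net_source <- sum((cf$a[unknown] - cf$b[unknown] * it$x) * vol)
  outflux <- sum(dir_g * (it$x[dir_i] - p_boundary))
  gap <- abs(net_source - outflux) / max(abs(outflux), abs(net_source), 1e-300)

  tum <- params_by_region$tumor
  ctr <- which.min(abs(.voxel_axis(geom)))
  report <- structure(list(
    method = method, iterations = it$iterations,
    final_residual = it$rel_residual, converged = it$converged,
    residual_history = it$residual_history,
    conservation_gap = gap, net_source_cm3_per_s = net_source,
    boundary_outflux_cm3_per_s = outflux,
    alpha = if (!is.null(tum)) alpha_parameter(tum, geom$R) else NA_real_,
    p_e = if (!is.null(tum)) effective_pressure(tum) else NA_real_,
    p_out = p_boundary,
    center_pressure = p[ctr, ctr, ctr],
    rim_velocity_cm_per_s = NA_real_, rim_velocity_um_per_s = NA_real_,
    N = m), class = "ifp_solve_report")
  structure(list(geom = geom, p = p, coeffs = cf, unknown = unknown,
                 report = report),
            class = "ifp_voxel_solution")
}

#' Face-centered Darcy velocities of a 3-D voxel solution
#'
#' For each axis, the velocity on interior faces is
#' `-K_face * dp / spacing` with harmonic-mean face conductivity. Faces
#' adjacent to exterior voxels use the adjacent interior conductivity and
#' the boundary pressure.
#'
#' @param solution an `ifp_voxel_solution` from [solve_3d()].
#' @return List with face arrays `ux` (`(n-1) x n x n`), `uy`, `uz` (cm/s)
#'   and cell-interpolated arrays `vx`, `vy`, `vz` (`n^3`).
#' @export
darcy_velocity_3d <- function(solution) {
  stopifnot(inherits(solution, "ifp_voxel_solution"))
  geom <- solution$geom
  n <- geom$n; h <- geom$spacing
  p <- solution$p
  K <- array(solution$coeffs$K, dim = dim(p))
  K[!solution$unknown] <- NA_real_
  u <- vector("list", 3)
  for (axis in 1:3) {
    idxL <- 1:(n - 1); idxR <- 2:n
    KL <- switch(axis, K[idxL, , , drop = FALSE], K[, idxL, , drop = FALSE],
                 K[, , idxL, drop = FALSE])
    KR <- switch(axis, K[idxR, , , drop = FALSE], K[, idxR, , drop = FALSE],
                 K[, , idxR, drop = FALSE])
    pL <- switch(axis, p[idxL, , , drop = FALSE], p[, idxL, , drop = FALSE],
                 p[, , idxL, drop = FALSE])
    pR <- switch(axis, p[idxR, , , drop = FALSE], p[, idxR, , drop = FALSE],
                 p[, , idxR, drop = FALSE])
    Kf <- 2 * KL * KR / (KL + KR)
    Kf[is.na(KL) & !is.na(KR)] <- KR[is.na(KL) & !is.na(KR)]
    Kf[is.na(KR) & !is.na(KL)] <- KL[is.na(KR) & !is.na(KL)]
    Kf[is.na(Kf)] <- 0
    u[[axis]] <- -Kf * (pR - pL) / h
  }
  pad_mean <- function(uf, axis) {
    v <- array(0, dim = c(n, n, n))
    zeros_dim <- c(n, n, n); zeros_dim[axis] <- 1
    z <- array(0, dim = zeros_dim)
    lo <- switch(axis, abind3(z, uf, 1), abind3(z, uf, 2), abind3(z, uf, 3))
    hi <- switch(axis, abind3(uf, z, 1), abind3(uf, z, 2), abind3(uf, z, 3))
    (lo + hi) / 2
  }
  list(ux = u[[1]], uy = u[[2]], uz = u[[3]],
       vx = pad_mean(u[[1]], 1), vy = pad_mean(u[[2]], 2),
       vz = pad_mean(u[[3]], 3))
}

# bind two arrays along an axis (tiny local helper; avoids an abind dep)
abind3 <- function(a, b, axis) {
  da <- dim(a); db <- dim(b)
  dd <- da; dd[axis] <- da[axis] + db[axis]
  out <- array(0, dim = dd)
  ia <- lapply(seq_along(dd), function(k) seq_len(da[k]))
  ib <- lapply(seq_along(dd), function(k) seq_len(db[k]))
  ib[[axis]] <- da[axis] + ib[[axis]]
  do.call(`[<-`, c(list(out), ia, list(a))) -> out
  do.call(`[<-`, c(list(out), ib, list(b))) -> out
  out
}

#' Radially averaged pressure of a 3-D voxel solution
#'
#' Bins interior voxels by center radius and averages the pressure per bin;
#' used to compare voxel solutions against the 1-D spherically symmetric
#' solutions.
#'
#' @param solution an `ifp_voxel_solution`.
#' @param nbins number of radial bins (default: one per voxel spacing).
#' @param r_max outer radius to include, cm (default: the geometry's
#'   Dirichlet radius).
#' @return Data frame with `r_cm` (bin mean radius), `p_mmHg` (bin mean
#'   pressure), `n_voxels`.
#' @export
radial_average <- function(solution, nbins = NULL, r_max = NULL) {
  stopifnot(inherits(solution, "ifp_voxel_solution"))
  geom <- solution$geom
  r <- .voxel_radii(geom)
  if (is.null(r_max)) r_max <- geom$R_out
  if (is.null(nbins)) nbins <- ceiling(r_max / geom$spacing)
  sel <- solution$unknown & r <= r_max
  bin <- pmin(nbins, floor(r[sel] / r_max * nbins) + 1L)
  data.frame(r_cm = as.numeric(tapply(r[sel], bin, mean)),
             p_mmHg = as.numeric(tapply(solution$p[sel], bin, mean)),
             n_voxels = as.integer(table(bin)))
}
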