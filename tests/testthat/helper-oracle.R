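# Independent brute-force oracle: node-centered conservative finite
# differences for (1/r^2) d/dr (r^2 K dp/dr) = b*p - a on [0, r_max] with a
# symmetry condition at the center and a Dirichlet value at r_max. Distinct
# discretisation (node-centered, control volumes around nodes) from the
# package's cell-centered scheme.

fd_sphere_oracle <- function(r_max, n, K_at, a_at, b_at, p_dirichlet = 0) {
  h <- r_max / n
  r <- (0:n) * h
  # conductivity sampled at the flux faces (midpoints), which lie strictly
  # inside a region when coefficient jumps sit on nodes; sources averaged
  # over the two half-cells of each node's control volume (exact for
  # piecewise-constant coefficients with jumps on nodes)
  a <- (a_at(pmax(r - h / 4, 0)) + a_at(r + h / 4)) / 2
  b <- (b_at(pmax(r - h / 4, 0)) + b_at(r + h / 4)) / 2
  rm_ <- (r[-1] + r[-(n + 1)]) / 2
  Km <- K_at(rm_)
  gm <- Km * rm_^2 / h                       # face conductance / (4*pi)
  m <- n                                     # unknown nodes 0..n-1
  dia <- numeric(m); lo <- numeric(m - 1); up <- numeric(m - 1); rhs <- numeric(m)
  for (j in seq_len(m)) {
    rj <- r[j]
    vl <- if (j == 1) 0 else rj - h / 2
    vr <- rj + h / 2
    vol <- (vr^3 - vl^3) / 3
    dia[j] <- b[j] * vol
    rhs[j] <- a[j] * vol
    if (j > 1) { dia[j] <- dia[j] + gm[j - 1]; lo[j - 1] <- -gm[j - 1] }
    dia[j] <- dia[j] + gm[j]
    if (j < m) up[j] <- -gm[j]
  }
  rhs[m] <- rhs[m] + gm[m] * p_dirichlet
  # Thomas elimination
  cp <- numeric(m); dp <- numeric(m)
  cp[1] <- up[1] / dia[1]; dp[1] <- rhs[1] / dia[1]
  for (i in 2:m) {
    denom <- dia[i] - lo[i - 1] * cp[i - 1]
    if (i < m) cp[i] <- up[i] / denom
    dp[i] <- (rhs[i] - lo[i - 1] * dp[i - 1]) / denom
  }
  x <- numeric(m); x[m] <- dp[m]
  for (i in (m - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  list(r = r, p = c(x, p_dirichlet))
}

# dimensionless isolated tumor with optional necrotic core (P(1) = 0)
fd_dimensionless_oracle <- function(alpha, rn_bar = 0, n = 10000) {
  fd_sphere_oracle(
    r_max = 1, n = n,
    K_at = function(r) rep(1, length(r)),
    a_at = function(r) alpha^2 * (r >= rn_bar - 1e-12),
    b_at = function(r) alpha^2 * (r >= rn_bar - 1e-12))
}

# dimensional two-region (tumor sphere inside a shell), Dirichlet p_far
fd_two_region_oracle <- function(tumor, shell, R, R_out, p_far = 0, n = 20000) {
  pe_t <- effective_pressure(tumor)
  pe_s <- effective_pressure(shell)
  fd_sphere_oracle(
    r_max = R_out, n = n,
    K_at = function(r) ifelse(r < R, tumor$K, shell$K),
    a_at = function(r) ifelse(r < R,
                              tumor$Lp * tumor$SV * pe_t +
                                tumor$lymph_coeff * tumor$pL,
                              shell$Lp * shell$SV * pe_s +
                                shell$lymph_coeff * shell$pL),
    b_at = function(r) ifelse(r < R,
                              tumor$Lp * tumor$SV + tumor$lymph_coeff,
                              shell$Lp * shell$SV + shell$lymph_coeff),
    p_dirichlet = p_far)
}
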