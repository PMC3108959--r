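#' Physiological tissue parameters for interstitial fluid transport
#'
#' Bundles the constants that drive Starling transcapillary filtration and
#' lymphatic drainage in one tissue type. Units are fixed package-wide to
#' cm, s and mmHg.
#'
#' @param K interstitial hydraulic conductivity, cm^2 mmHg^-1 s^-1 (> 0).
#' @param Lp hydraulic conductivity of the microvascular wall,
#'   cm mmHg^-1 s^-1 (>= 0).
#' @param SV vascular surface area per unit tissue volume, cm^-1 (>= 0).
#' @param pv vascular (microvascular) pressure, mmHg.
#' @param sigma average osmotic reflection coefficient for plasma proteins,
#'   dimensionless in \[0, 1\].
#' @param pi_v plasma osmotic pressure, mmHg.
#' @param pi_i interstitial osmotic pressure, mmHg.
#' @param lymph_coeff lymphatic filtration coefficient, the product of the
#'   lymphatic wall hydraulic conductivity and the lymphatic surface density,
#'   mmHg^-1 s^-1 (>= 0). Solid tumors have no functional lymphatics, so a
#'   tumor instance uses 0.
#' @param pL hydrostatic pressure of the lymphatics, mmHg.
#'
#' @return An object of class `tissue_parameters` (a validated named list).
#' @seealso [baseline_tissue_parameters()] for the shipped baseline values,
#'   [effective_pressure()], [steady_state_pressure()], [alpha_parameter()].
#' @export
#' @examples
#' tumor <- tissue_parameters(K = 4.13e-8, Lp = 2.8e-7, SV = 200,
#'                            pv = 15.6, sigma = 0.82, pi_v = 20, pi_i = 15,
#'                            lymph_coeff = 0, pL = 0)
#' effective_pressure(tumor)
tissue_parameters <- function(K, Lp, SV, pv, sigma, pi_v, pi_i,
                              lymph_coeff = 0, pL = 0) {
  p <- list(K = K, Lp = Lp, SV = SV, pv = pv, sigma = sigma,
            pi_v = pi_v, pi_i = pi_i, lymph_coeff = lymph_coeff, pL = pL)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("tissue parameter '", nm, "' must be a single finite number",
           call. = FALSE)
  }
  if (p$K <= 0) stop("tissue parameter 'K' must be > 0", call. = FALSE)
  if (p$Lp < 0) stop("tissue parameter 'Lp' must be >= 0", call. = FALSE)
  if (p$SV < 0) stop("tissue parameter 'SV' must be >= 0", call. = FALSE)
  if (p$sigma < 0 || p$sigma > 1)
    stop("tissue parameter 'sigma' must lie in [0, 1]", call. = FALSE)
  if (p$lymph_coeff < 0)
    stop("tissue parameter 'lymph_coeff' must be >= 0", call. = FALSE)
  structure(p, class = "tissue_parameters")
}

#' @export
print.tissue_parameters <- function(x, ...) {
  cat("Tissue parameters (cm, s, mmHg):\n")
  cat(sprintf("  K  = %.4g cm^2/(mmHg s)   Lp = %.4g cm/(mmHg s)   S/V = %.4g 1/cm\n",
              x$K, x$Lp, x$SV))
  cat(sprintf("  pv = %.4g  sigma = %.3g  pi_v = %.4g  pi_i = %.4g  (mmHg)\n",
              x$pv, x$sigma, x$pi_v, x$pi_i))
  cat(sprintf("  lymphatic coefficient = %.4g 1/(mmHg s), pL = %.4g mmHg\n",
              x$lymph_coeff, x$pL))
  cat(sprintf("  derived: p_e = %.4g mmHg", effective_pressure(x)))
  if (x$Lp * x$SV + x$lymph_coeff > 0)
    cat(sprintf(", p_ss = %.4g mmHg", steady_state_pressure(x)))
  cat("\n")
  invisible(x)
}

#' Baseline tissue parameters
#'
#' The baseline parameter set shipped with the package (also available as the
#' `inst/extdata/baseline.yaml` configuration): the classic normal-tissue and
#' tumor values of Jain and Baxter used throughout the tumor
#' interstitial-transport literature. Tumor tissue carries no lymphatics.
#'
#' @param tissue `"tumor"` or `"normal"`.
#' @return A [tissue_parameters()] object.
#' @export
#' @examples
#' alpha_parameter(baseline_tissue_parameters("tumor"), R = 1)
baseline_tissue_parameters <- function(tissue = c("tumor", "normal")) {
  tissue <- match.arg(tissue)
  if (tissue == "tumor") {
    tissue_parameters(K = 4.13e-8, Lp = 2.8e-7, SV = 200,
                      pv = 15.6, sigma = 0.82, pi_v = 20, pi_i = 15,
                      lymph_coeff = 0, pL = 0)
  } else {
    tissue_parameters(K = 8.53e-9, Lp = 0.36e-7, SV = 70,
                      pv = 15.6, sigma = 0.91, pi_v = 20, pi_i = 10,
                      lymph_coeff = 0, pL = 0)
  }
}

#' Parameters of a necrotic (dead) region
#'
#' Necrotic tissue has no functioning blood or lymph vessels: both the
#' Starling source and the lymphatic sink vanish and pressure obeys the
#' Laplace equation. Hydraulic conductivity is kept from the supplied viable
#' tissue.
#'
#' @param params viable-tissue [tissue_parameters()] supplying `K`.
#' @return A [tissue_parameters()] object with `Lp = SV = lymph_coeff = 0`.
#' @export
necrotic_parameters <- function(params) {
  stopifnot(inherits(params, "tissue_parameters"))
  tissue_parameters(K = params$K, Lp = 0, SV = 0, pv = params$pv,
                    sigma = params$sigma, pi_v = params$pi_v,
                    pi_i = params$pi_i, lymph_coeff = 0, pL = params$pL)
}

#' Effective pressure
#'
#' The interstitial pressure at which net transcapillary filtration is zero:
#' `p_e = pv - sigma * (pi_v - pi_i)`. It depends only on the pressures and
#' the reflection coefficient, not on any conductivity.
#'
#' @param params a [tissue_parameters()] object.
#' @return Effective pressure in mmHg.
#' @export
effective_pressure <- function(params) {
  stopifnot(inherits(params, "tissue_parameters"))
  params$pv - params$sigma * (params$pi_v - params$pi_i)
}

#' Steady-state pressure
#'
#' The interstitial pressure at which vascular efflux and lymphatic influx
#' balance: `(Lp*SV*p_e + lymph_coeff*pL) / (Lp*SV + lymph_coeff)`. With no
#' lymphatics it equals the effective pressure exactly.
#'
#' @inheritParams effective_pressure
#' @return Steady-state pressure in mmHg.
#' @export
steady_state_pressure <- function(params) {
  stopifnot(inherits(params, "tissue_parameters"))
  fb <- params$Lp * params$SV
  fl <- params$lymph_coeff
  if (fb + fl <= 0)
    stop("steady-state pressure is undefined for dead tissue ",
         "(Lp*SV + lymph_coeff = 0)", call. = FALSE)
  (fb * effective_pressure(params) + fl * params$pL) / (fb + fl)
}

#' Dimensionless resistance ratio alpha
#'
#' `alpha = R * sqrt((Lp*SV + lymph_coeff) / K)`, the ratio of interstitial
#' to vascular flow resistance for a sphere of radius `R`. It controls how
#' sharply the interstitial pressure plateaus at the effective pressure in
#' the tumor core.
#'
#' @inheritParams effective_pressure
#' @param R sphere radius in cm (> 0).
#' @return Dimensionless alpha.
#' @export
alpha_parameter <- function(params, R) {
  stopifnot(inherits(params, "tissue_parameters"))
  if (!is.numeric(R) || any(R <= 0)) stop("R must be > 0", call. = FALSE)
  R * filtration_rate_coefficient(params)
}

# sqrt((Lp*SV + lymph_coeff)/K), 1/cm: the inverse hydraulic screening length
filtration_rate_coefficient <- function(params) {
  sqrt((params$Lp * params$SV + params$lymph_coeff) / params$K)
}

#' Starling transcapillary source
#'
#' Volumetric filtration rate from the vasculature into the interstitium per
#' unit tissue volume: `Lp*SV*(pv - p - sigma*(pi_v - pi_i)) =
#' Lp*SV*(p_e - p)`. Positive when the interstitial pressure is below the
#' effective pressure.
#'
#' @inheritParams effective_pressure
#' @param p interstitial fluid pressure, mmHg (vectorised).
#' @return Source in s^-1.
#' @export
starling_source <- function(params, p) {
  stopifnot(inherits(params, "tissue_parameters"))
  params$Lp * params$SV * (effective_pressure(params) - p)
}

#' Lymphatic drainage sink
#'
#' Volumetric flow rate from the interstitium into the lymphatics per unit
#' tissue volume: `lymph_coeff * (p - pL)`. Identically zero for tumor tissue,
#' which has no functional lymphatics.
#'
#' @inheritParams starling_source
#' @return Sink in s^-1.
#' @export
lymph_sink <- function(params, p) {
  stopifnot(inherits(params, "tissue_parameters"))
  params$lymph_coeff * (p - params$pL)
}
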