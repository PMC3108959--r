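# Configuration loading/validation and file export: CSV profiles, legacy-VTK
# 3-D fields, JSON reports and labeled voxel masks. All outputs are
# deterministic for a fixed configuration (no timestamps inside data files).

.TISSUE_KEYS <- c("K", "Lp", "SV", "pv", "sigma", "pi_v", "pi_i",
                  "lymph_coeff", "pL")

.default_config <- function() {
  list(geometry = list(Rn_cm = 0, n_per_axis = 32L),
       boundary = list(kind = "isolated", p_surr_mmHg = 0, p_far_mmHg = 0),
       solver = list(method = "direct", tol = 1e-6, relaxation = 0.75,
                     max_iter = 100000L, n_cells = 1000L),
       analysis = list(eps = 0.01, radii_cm = c(0.1, 0.25, 0.5, 1.0),
                       rn_bar = 0),
       output = list(prefix = "ifpsim_run"))
}

# merge user block over defaults, logging every applied default
.merge_block <- function(user, defaults, block) {
  if (is.null(user)) {
    message(sprintf("config: block '%s' missing, using defaults (%s)", block,
                    paste(names(defaults), collapse = ", ")))
    return(defaults)
  }
  extra <- setdiff(names(user), names(defaults))
  if (length(extra) && !(block %in% c("geometry")))
    stop("config: unknown key(s) in '", block, "': ",
         paste(extra, collapse = ", "), call. = FALSE)
  for (k in names(defaults)) {
    if (is.null(user[[k]])) {
      user[[k]] <- defaults[[k]]
      message(sprintf("config: applied default %s.%s = %s", block, k,
                      paste(format(defaults[[k]]), collapse = ",")))
    }
  }
  user
}

#' Load and validate a run configuration
#'
#' Reads a YAML (`.yaml`/`.yml`) or JSON (`.json`) configuration with blocks
#' `tissues` (named `tumor` and `normal`, each with exactly the keys
#' `K, Lp, SV, pv, sigma, pi_v, pi_i, lymph_coeff, pL`; units cm, s, mmHg),
#' `geometry` (`R_cm`, optional `Rn_cm`, `R_out_cm`, `n_per_axis`),
#' `boundary` (`kind` = `"isolated"` or `"embedded"`, `p_surr_mmHg`,
#' `p_far_mmHg`), `solver`, `analysis` and `output`. Missing optional keys
#' are filled with defaults (solver tolerance `1e-6`, relaxation `0.75`,
#' analysis eps `0.01`, ...) and every applied default is logged via
#' `message()`. Violated invariants raise an error naming the offending
#' key.
#'
#' @param path configuration file path.
#' @return An object of class `ifp_config`.
#' @export
#' @examples
#' cfg <- load_config(system.file("extdata", "baseline.yaml", package = "ifpsim"))
#' cfg$tissues$tumor
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$tissues))
    stop("config: missing required block 'tissues'", call. = FALSE)
  tissues <- list()
  for (tn in c("tumor", "normal")) {
    blk <- raw$tissues[[tn]]
    if (is.null(blk))
      stop("config: missing tissue block '", tn, "'", call. = FALSE)
    missing_k <- setdiff(.TISSUE_KEYS, names(blk))
    extra_k <- setdiff(names(blk), .TISSUE_KEYS)
    if (length(missing_k))
      stop("config: tissue '", tn, "' is missing key(s): ",
           paste(missing_k, collapse = ", "), call. = FALSE)
    if (length(extra_k))
      stop("config: tissue '", tn, "' has unknown key(s): ",
           paste(extra_k, collapse = ", "), call. = FALSE)
    tissues[[tn]] <- do.call(tissue_parameters, blk[.TISSUE_KEYS])
  }
  def <- .default_config()
  geometry <- .merge_block(raw$geometry, def$geometry, "geometry")
  if (is.null(geometry$R_cm))
    stop("config: geometry is missing key 'R_cm'", call. = FALSE)
  if (geometry$R_cm <= 0) stop("config: R_cm must be > 0", call. = FALSE)
  if (geometry$Rn_cm < 0 || geometry$Rn_cm > geometry$R_cm)
    stop("config: Rn_cm must lie in [0, R_cm]", call. = FALSE)
  boundary <- .merge_block(raw$boundary, def$boundary, "boundary")
  if (!boundary$kind %in% c("isolated", "embedded"))
    stop("config: boundary.kind must be 'isolated' or 'embedded'", call. = FALSE)
  if (is.null(geometry$R_out_cm)) {
    geometry$R_out_cm <- if (boundary$kind == "embedded") 3 * geometry$R_cm
                         else geometry$R_cm
    if (boundary$kind == "embedded")
      message("config: applied default geometry.R_out_cm = 3*R_cm = ",
              geometry$R_out_cm)
  }
  if (geometry$R_out_cm < geometry$R_cm)
    stop("config: R_out_cm must be >= R_cm", call. = FALSE)
  solver <- .merge_block(raw$solver, def$solver, "solver")
  if (!solver$method %in% c("direct", "sor", "pcg"))
    stop("config: solver.method must be one of direct, sor, pcg", call. = FALSE)
  if (solver$tol <= 0 || solver$tol >= 1)
    stop("config: solver.tol must lie in (0, 1)", call. = FALSE)
  analysis <- .merge_block(raw$analysis, def$analysis, "analysis")
  if (analysis$eps <= 0 || analysis$eps >= 0.5)
    stop("config: analysis.eps must lie in (0, 0.5)", call. = FALSE)
  output <- .merge_block(raw$output, def$output, "output")
  structure(list(tissues = tissues, geometry = geometry, boundary = boundary,
                 solver = solver, analysis = analysis, output = output,
                 source_path = normalizePath(path)),
            class = "ifp_config")
}

# plain-list view of a config (for JSON audit trails)
.config_as_list <- function(cfg) {
  list(tissues = lapply(cfg$tissues, function(t) unclass(t)),
       geometry = cfg$geometry, boundary = cfg$boundary,
       solver = cfg$solver, analysis = cfg$analysis, output = cfg$output)
}

#' Write a radial profile as CSV
#'
#' Columns: `rbar, r_cm, P, p_mmHg, U, u_cm_per_s, u_um_per_s, phiB_per_s`
#' (plus `region` for two-region profiles). `.` decimal, comma separator,
#' mandatory header.
#'
#' @param profile an `ifp_profile` data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(is.data.frame(profile))
  cols <- c("rbar", "r_cm", "P", "p_mmHg", "U", "u_cm_per_s", "u_um_per_s",
            "phiB_per_s", "region")
  cols <- intersect(cols, names(profile))
  utils::write.csv(profile[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a JSON run report
#'
#' Serialises a solve report (and, when given, the resolved configuration
#' that produced it, as an audit trail) to JSON. Numbers keep full
#' precision.
#'
#' @param report an `ifp_solve_report` (or any list of scalars).
#' @param path output file.
#' @param config optional `ifp_config` to embed.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path, config = NULL) {
  out <- unclass(report)
  if (!is.null(config)) out$config <- .config_as_list(config)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write a 3-D voxel solution as legacy ASCII VTK
#'
#' `STRUCTURED_POINTS` dataset with point data on voxel centers: scalars
#' `pressure_mmHg` and `source_per_s` (net volumetric source, zero in
#' necrotic and exterior voxels) and the cell-interpolated vector field
#' `velocity_cm_per_s`.
#'
#' @param solution an `ifp_voxel_solution` from [solve_3d()].
#' @param path output file (conventionally `.vtk`).
#' @return `path`, invisibly.
#' @export
write_vtk <- function(solution, path) {
  stopifnot(inherits(solution, "ifp_voxel_solution"))
  geom <- solution$geom
  n <- geom$n; h <- geom$spacing
  num <- function(x) sprintf("%.9g", x)
  src <- solution$coeffs$a - solution$coeffs$b * as.numeric(solution$p)
  src[is.na(src)] <- 0
  vel <- darcy_velocity_3d(solution)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "ifpsim interstitial fluid field",
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", n, n, n),
               sprintf("ORIGIN %s %s %s", num(geom$origin + h / 2),
                       num(geom$origin + h / 2), num(geom$origin + h / 2)),
               sprintf("SPACING %s %s %s", num(h), num(h), num(h)),
               sprintf("POINT_DATA %d", n^3),
               "SCALARS pressure_mmHg double 1",
               "LOOKUP_TABLE default"), con)
  writeLines(num(as.numeric(solution$p)), con)
  writeLines(c("SCALARS source_per_s double 1", "LOOKUP_TABLE default"), con)
  writeLines(num(src), con)
  writeLines("VECTORS velocity_cm_per_s double", con)
  writeLines(paste(num(as.numeric(vel$vx)), num(as.numeric(vel$vy)),
                   num(as.numeric(vel$vz))), con)
  invisible(path)
}

#' Write / read a labeled voxel mask
#'
#' Plain-text format: first line a JSON header (`shape`, `spacing_cm`,
#' `origin_cm`, `label_map`, generating radii when known), remaining lines
#' the integer labels in x-fastest order.
#'
#' @param geom a `voxel_geometry`.
#' @param path output file.
#' @return `path` invisibly (`write_voxel_mask`); a `voxel_geometry`
#'   (`read_voxel_mask`).
#' @export
write_voxel_mask <- function(geom, path) {
  stopifnot(inherits(geom, "voxel_geometry"))
  header <- jsonlite::toJSON(list(shape = dim(geom$labels),
                                  spacing_cm = geom$spacing,
                                  origin_cm = geom$origin,
                                  R_cm = geom$R, Rn_cm = geom$Rn,
                                  R_out_cm = geom$R_out,
                                  label_map = as.list(geom$label_map)),
                             auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(header), con)
  # one z-slice worth of labels per line
  lab <- matrix(as.integer(geom$labels), nrow = prod(dim(geom$labels)[1:2]))
  writeLines(apply(lab, 2, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname write_voxel_mask
#' @export
read_voxel_mask <- function(path) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[1])
  labels <- as.integer(unlist(strsplit(lines[-1], " ", fixed = TRUE)))
  labels <- array(labels, dim = unlist(header$shape))
  structure(list(labels = labels, spacing = header$spacing_cm,
                 origin = header$origin_cm, n = dim(labels)[1],
                 R = header$R_cm, Rn = header$Rn_cm, R_out = header$R_out_cm,
                 label_map = unlist(header$label_map)),
            class = "voxel_geometry")
}
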