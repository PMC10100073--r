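#' Pipeline configuration
#'
#' Single validated document of all processing defaults: strain-estimation
#' window and lag, silicone calibration, the standardized stress window,
#' class thresholds and the segmentation/subtyping constants. Unknown keys
#' are rejected.
#'
#' @param window_axial_um,window_lateral_um Strain averaging window, um.
#' @param axial_lag_px Axial lag of the vector method, px.
#' @param amp_floor Vector-sum validity floor (see [vector_strain()]).
#' @param E_sil Reference silicone Young's modulus, kPa (used when the
#'   series metadata carries none).
#' @param stress_mode Stress standardization per lateral `"column"` or
#'   `"global"` per frame.
#' @param stress_window_kPa Stress window for the tangent modulus, kPa.
#' @param standardized_stress_kPa Reporting stress, kPa.
#' @param max_modulus_kPa Artifact clamp for recovered moduli.
#' @param max_invalid_fraction Per-pixel tolerated invalid-frame fraction.
#' @param class_ranges A [class_ranges()].
#' @param depth_limit_um Non-signal counting depth below the interface.
#' @param min_gland_area_um2 Analysis-ROI area for class presence and
#'   gland-like components, um^2.
#' @param gland_min_components,gland_max_coverage Gland-like decision
#'   constants.
#' @param loss_floor Non-signal fraction treated as "no loss".
#' @param seed Default seed for simulation helpers.
#' @return Object of class `"coce_config"` (a validated named list).
#' @export
coce_config <- function(window_axial_um = 100, window_lateral_um = 100,
                        axial_lag_px = 3L, amp_floor = 0.25,
                        E_sil = 100, stress_mode = c("column", "global"),
                        stress_window_kPa = c(3, 5),
                        standardized_stress_kPa = 4,
                        max_modulus_kPa = 5000,
                        max_invalid_fraction = 0.3,
                        class_ranges = coce::class_ranges(),
                        depth_limit_um = 500,
                        min_gland_area_um2 = 110 * 110,
                        gland_min_components = 2L,
                        gland_max_coverage = 0.7,
                        loss_floor = 0.02,
                        seed = 1L) {
  stress_mode <- match.arg(stress_mode)
  cfg <- list(window_axial_um = window_axial_um,
              window_lateral_um = window_lateral_um,
              axial_lag_px = as.integer(axial_lag_px),
              amp_floor = amp_floor, E_sil = E_sil,
              stress_mode = stress_mode,
              stress_window_kPa = stress_window_kPa,
              standardized_stress_kPa = standardized_stress_kPa,
              max_modulus_kPa = max_modulus_kPa,
              max_invalid_fraction = max_invalid_fraction,
              class_ranges = class_ranges,
              depth_limit_um = depth_limit_um,
              min_gland_area_um2 = min_gland_area_um2,
              gland_min_components = as.integer(gland_min_components),
              gland_max_coverage = gland_max_coverage,
              loss_floor = loss_floor,
              seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "coce_config")
}

validate_config <- function(cfg) {
  pos <- c("window_axial_um", "window_lateral_um", "axial_lag_px", "E_sil",
           "standardized_stress_kPa", "max_modulus_kPa", "depth_limit_um",
           "min_gland_area_um2")
  for (k in pos)
    if (!is_scalar_num(cfg[[k]]) || cfg[[k]] <= 0)
      coce_stop("config key '%s' must be a positive number", k)
  if (cfg$amp_floor < 0 || cfg$amp_floor > 1)
    coce_stop("amp_floor must lie in [0, 1]")
  sw <- cfg$stress_window_kPa
  if (length(sw) != 2 || sw[1] >= sw[2] || sw[1] <= 0)
    coce_stop("stress_window_kPa must be an increasing positive pair")
  if (!(sw[1] < cfg$standardized_stress_kPa &&
        cfg$standardized_stress_kPa < sw[2]))
    coce_stop("standardized stress must lie inside the stress window")
  if (cfg$max_invalid_fraction < 0 || cfg$max_invalid_fraction > 1 ||
      cfg$loss_floor < 0 || cfg$loss_floor >= 0.5 ||
      cfg$gland_max_coverage <= 0 || cfg$gland_max_coverage > 1)
    coce_stop("fractional config keys out of range")
  if (!inherits(cfg$class_ranges, "class_ranges"))
    coce_stop("class_ranges must be built with class_ranges()")
  invisible(cfg)
}

# Apply named overrides to an existing config, re-validating.
modify_config <- function(config, ...) {
  dots <- list(...)
  if (length(dots) == 0) return(config)
  unknown <- setdiff(names(dots), names(config))
  if (length(unknown))
    coce_stop("unknown config key(s): %s", paste(unknown, collapse = ", "))
  config[names(dots)] <- dots
  validate_config(config)
  structure(config, class = "coce_config")
}

#' Read / write a pipeline configuration
#'
#' JSON or YAML by file extension. Parsing a written file reproduces the
#' configuration exactly; unknown keys in a file are rejected.
#'
#' @param config A [coce_config()].
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return `read_config()` returns a `"coce_config"`; `write_config()`
#'   returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "coce_config"))
  x <- unclass(config)
  x$class_ranges <- unclass(x$class_ranges)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path)
  } else coce_stop("unsupported config extension '.%s'", ext)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else coce_stop("unsupported config extension '.%s'", ext)
  cr <- x$class_ranges
  x$class_ranges <- NULL
  defaults <- coce_config()
  unknown <- setdiff(names(x), names(defaults))
  if (length(unknown))
    coce_stop("unknown config key(s) in %s: %s", path,
              paste(unknown, collapse = ", "))
  x$class_ranges <- do.call(class_ranges, as.list(cr))
  do.call(coce_config, x)
}

#' @export
print.coce_config <- function(x, ...) {
  cat("C-OCE pipeline configuration\n")
  cat(sprintf("  window %g x %g um, lag %d px, amp floor %g\n",
              x$window_axial_um, x$window_lateral_um, x$axial_lag_px,
              x$amp_floor))
  cat(sprintf("  stress window %g-%g kPa at %g kPa, E_sil %g kPa (%s stress)\n",
              x$stress_window_kPa[1], x$stress_window_kPa[2],
              x$standardized_stress_kPa, x$E_sil, x$stress_mode))
  cr <- x$class_ranges
  cat(sprintf("  classes: floor %g | stroma %g-%g | cancer %g-%g | very high >%g kPa\n",
              cr$signal_floor, cr$stroma[1], cr$stroma[2], cr$cancer_low,
              cr$cancer_high, cr$cancer_high))
  invisible(x)
}
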