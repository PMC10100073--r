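# Synthetic cohort generation: geometry templates per morphological subtype.
#
# Template stiffness values are the class means measured for colorectal
# tissue (mucosa 58, adenoma 46, stroma 295, glandular cancer 724 kPa);
# non-glandular (high-grade) foci are placed at 1100 kPa, comfortably
# inside the 703-1418 kPa very-high range, so that a reconstructed
# homogeneous focus does not straddle the 950 kPa class boundary. Tissue
# classes carry a mild stiffening nonlinearity: E0 is chosen 5% below the
# target tangent modulus at 4 kPa and beta makes up the difference, so the
# true map at the standardized stress equals the class value exactly.

tissue_class <- function(label, name, E4, nonlinear = TRUE) {
  if (nonlinear) {
    mechanical_class(label, name, E0 = 0.95 * E4, beta = 0.05 * E4 / 4)
  } else {
    mechanical_class(label, name, E0 = E4)
  }
}

mucin_class <- function(label) {
  mechanical_class(label, "mucin", E0 = 30, beta = 0, is_nonsignal = TRUE)
}

COHORT_SUBTYPES <- c("normal", "adenoma", "low_grade", "high_grade",
                     "cribriform", "mac")

# Expected subtype call for each template when its ground-truth map is
# segmented with default settings (used by tests and the CLI round trip).
template_expected_call <- function(subtype) {
  switch(subtype,
         normal = , adenoma = "NON_CANCEROUS",
         low_grade = "LOW_GRADE_CRAC",
         high_grade = "HIGH_GRADE_CRAC",
         cribriform = "CRAC_CRIBRIFORM",
         mac = "MAC")
}

# Place random non-overlapping-ish shapes of a target class until the
# requested fraction of the tissue area is covered (counted on a scratch
# raster). Returns the shape list.
fill_shapes <- function(target_fraction, width_um, depth_um, class_label,
                        rx_range, rz_range, max_iter = 400L,
                        min_shapes = 0L) {
  shapes <- list()
  if (target_fraction <= 0) return(shapes)
  nx <- 64L; nz <- 64L
  xs <- (seq_len(nx) - 0.5) * width_um / nx
  zs <- (seq_len(nz) - 0.5) * depth_um / nz
  covered <- matrix(FALSE, nz, nx)
  for (i in seq_len(max_iter)) {
    if (length(shapes) >= min_shapes && mean(covered) >= target_fraction)
      break
    rx <- stats::runif(1, rx_range[1], rx_range[2])
    rz <- stats::runif(1, rz_range[1], rz_range[2])
    cx <- stats::runif(1, rx, width_um - rx)
    cz <- stats::runif(1, rz, depth_um - rz)
    shapes[[length(shapes) + 1L]] <-
      shape_ellipse(cx, cz, rx, rz, class_label)
    covered <- covered |
      outer((zs - cz)^2 / rz^2, (xs - cx)^2 / rx^2, "+") <= 1
  }
  shapes
}

# Build the phantom_spec for one cohort sample.
cohort_phantom <- function(subtype, cancer_fraction, depth_px, lateral_px,
                           axial_pixel_um, lateral_pixel_um,
                           silicone_thickness_um, E_sil) {
  tissue_depth_um <- (depth_px -
    round(silicone_thickness_um / axial_pixel_um)) * axial_pixel_um
  width_um <- lateral_px * lateral_pixel_um
  base <- function(bg, classes, shapes = list()) {
    phantom_spec(depth_px = depth_px, lateral_px = lateral_px,
                 axial_pixel_um = axial_pixel_um,
                 lateral_pixel_um = lateral_pixel_um,
                 silicone_thickness_um = silicone_thickness_um,
                 E_sil = E_sil, background = bg, classes = classes,
                 shapes = shapes)
  }
  gland_r <- c(130, 260)  # ellipse semi-axes, um
  switch(subtype,
    normal = base(1, list(tissue_class(1, "mucosa", 58))),
    adenoma = base(1, list(tissue_class(1, "adenoma", 46))),
    low_grade = {
      shapes <- fill_shapes(cancer_fraction, width_um, tissue_depth_um,
                            2L, gland_r, gland_r * 0.7, min_shapes = 2L)
      base(1, list(tissue_class(1, "stroma", 295),
                   tissue_class(2, "gland", 724)), shapes)
    },
    high_grade = {
      # one solid very stiff focus growing down from the mucosal side;
      # both extents are kept at or above one analysis ROI (110 um) so the
      # focus is not thinner than the method's spatial resolution
      shapes <- list()
      if (cancer_fraction > 0) {
        area <- cancer_fraction * width_um * tissue_depth_um
        h <- min(max(110, cancer_fraction * tissue_depth_um),
                 tissue_depth_um - 160)
        w <- min(width_um, max(110, area / h))
        shapes <- list(shape_rect(width_um / 2, 80 + h / 2, w, h, 2L))
      }
      base(1, list(tissue_class(1, "stroma", 295),
                   tissue_class(2, "nonglandular", 1100)), shapes)
    },
    cribriform = {
      # laterally spaced gland rings with wide non-signal lumina in the
      # superficial band; lumina are large enough that their cores stay
      # non-signal after window averaging
      n_glands <- 3L
      slot <- width_um / n_glands
      shapes <- list()
      for (g in seq_len(n_glands)) {
        rx <- min(stats::runif(1, 280, 310), slot / 2 - 15)
        rz <- stats::runif(1, 180, 230)
        cx <- (g - 0.5) * slot + stats::runif(1, -30, 30)
        cz <- stats::runif(1, rz + 20, max(rz + 30, 480 - rz))
        shapes[[2 * g - 1L]] <- shape_ellipse(cx, cz, rx, rz, 2L)
        shapes[[2 * g]] <- shape_ellipse(cx, cz, 0.55 * rx, 0.55 * rz, 3L)
      }
      base(1, list(tissue_class(1, "stroma", 295),
                   tissue_class(2, "cribriform_gland", 724),
                   mucin_class(3)), shapes)
    },
    mac = {
      # mucin pockets dominating the superficial 500 um band (>50% loss),
      # plus one ROI-sized very stiff cancer-cell cluster on a deep
      # stromal wall and two sub-ROI satellite clusters
      shapes <- fill_shapes(0.75, width_um, min(tissue_depth_um, 500),
                            3L, c(200, 380), c(120, 220))
      k <- length(shapes)
      deep <- min(tissue_depth_um - 130, 560)
      shapes[[k + 1L]] <- shape_ellipse(
        stats::runif(1, 160, width_um - 160), deep, 140, 110, 2L)
      for (g in 1:2)
        shapes[[k + 1L + g]] <- shape_ellipse(
          stats::runif(1, 60, width_um - 60),
          stats::runif(1, deep - 60, deep + 60), 50, 40, 2L)
      base(1, list(tissue_class(1, "stroma", 295),
                   tissue_class(2, "cancer_cluster", 1100),
                   mucin_class(3)), shapes)
    },
    coce_stop("unknown subtype template '%s'", subtype))
}

#' Generate a synthetic study cohort
#'
#' Draws `n_samples` phantoms from a mix of morphological subtype templates
#' (gland nests in stroma for low-grade adenocarcinoma, solid very stiff
#' fields for high-grade, wide-lumen glands for the cribriform pattern,
#' dominant mucin pockets for mucinous adenocarcinoma, homogeneous soft
#' tissue for normal colon and adenoma) and simulates the compression
#' series for each. Cancer-bearing samples receive target cancer-area
#' fractions spread evenly across `cancer_fraction_range`; the achieved
#' fraction is recounted from the rasterized label map and reported in the
#' ground truth. Reproducible for a fixed seed.
#'
#' The default mix mirrors a surgical colorectal series dominated by
#' non-cancerous tissue with low-grade adenocarcinoma as the most common
#' malignant subtype.
#'
#' @param n_samples Number of samples (>= 1).
#' @param class_mix Named numeric vector of subtype weights over
#'   `r paste(COHORT_SUBTYPES, collapse = ", ")`; need not sum to 1.
#' @param cancer_fraction_range Range of target cancer-area fractions for
#'   cancer-bearing samples.
#' @param seed Integer seed.
#' @param depth_px,lateral_px,axial_pixel_um,lateral_pixel_um Phantom grid.
#' @param silicone_thickness_um,E_sil Reference layer.
#' @param n_frames,max_stress_kPa,snr_db Acquisition settings.
#' @return List of length `n_samples`; each element has `series`, `truth`,
#'   `subtype`, `target_fraction`.
#' @export
make_cohort <- function(n_samples, class_mix = c(normal = 0.35,
                                                 adenoma = 0.10,
                                                 low_grade = 0.25,
                                                 high_grade = 0.15,
                                                 cribriform = 0.08,
                                                 mac = 0.07),
                        cancer_fraction_range = c(0.05, 0.8), seed = 1L,
                        depth_px = 250L, lateral_px = 160L,
                        axial_pixel_um = 4, lateral_pixel_um = 12.5,
                        silicone_thickness_um = 300, E_sil = 100,
                        n_frames = 40L, max_stress_kPa = 6, snr_db = 25) {
  if (n_samples < 1) coce_stop("n_samples must be >= 1")
  if (length(class_mix) == 0 || sum(class_mix) <= 0)
    coce_stop("class_mix must contain positive weights")
  unknown <- setdiff(names(class_mix), COHORT_SUBTYPES)
  if (length(unknown))
    coce_stop("unknown subtype(s) in class_mix: %s",
              paste(unknown, collapse = ", "))
  fr <- cancer_fraction_range
  if (any(fr < 0) || any(fr > 1) || fr[1] > fr[2])
    coce_stop("cancer_fraction_range must be an ordered pair in [0, 1]")

  local_seed(seed, {
    subtypes <- sample(names(class_mix), n_samples, replace = TRUE,
                       prob = class_mix / sum(class_mix))
    is_cancer <- !subtypes %in% c("normal", "adenoma")
    fractions <- numeric(n_samples)
    nc <- sum(is_cancer)
    if (nc > 0)
      fractions[is_cancer] <- sample(seq(fr[1], fr[2], length.out = nc))
    out <- vector("list", n_samples)
    for (i in seq_len(n_samples)) {
      spec <- cohort_phantom(subtypes[i], fractions[i], depth_px, lateral_px,
                             axial_pixel_um, lateral_pixel_um,
                             silicone_thickness_um, E_sil)
      sim <- simulate_compression_series(
        build_phantom(spec),
        acquisition_spec(n_frames = n_frames, max_stress_kPa = max_stress_kPa,
                         snr_db = snr_db,
                         seed = sample.int(.Machine$integer.max, 1)))
      out[[i]] <- list(series = sim$series, truth = sim$truth,
                       subtype = subtypes[i], target_fraction = fractions[i])
    }
    out
  })
}
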