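CLASS_LEVELS <- c(NON_SIGNAL = 0L, LOW = 1L, STROMA = 2L,
                  CANCER_GLAND = 3L, VERY_HIGH = 4L)

SUBTYPE_CALLS <- c("NON_CANCEROUS", "LOW_GRADE_CRAC", "HIGH_GRADE_CRAC",
                   "CRAC_CRIBRIFORM", "MAC", "INDETERMINATE")

#' Stiffness class ranges for colorectal tissue segmentation
#'
#' Default thresholds follow the stiffness spectra measured for colorectal
#' tissue: cancer cells occupy 520-1418 kPa with glandular (gland-like)
#' structures at 520-950 kPa and non-glandular, very stiff foci above
#' 950 kPa; tumour stroma spans 92-515 kPa; anything softer but above the
#' 1 kPa signal floor (mucosa, submucosa, adenoma) is low-stiffness tissue.
#' The 515-520 kPa gap between the printed stroma maximum and the cancer
#' threshold is assigned to stroma — conservative toward fewer false cancer
#' calls.
#'
#' @param cancer_low,cancer_high Glandular-cancer class bounds, kPa
#'   (inclusive).
#' @param cancer_max Largest stiffness observed in cancer, kPa
#'   (documentation; values above remain in the very-high class).
#' @param stroma Two-element stroma range, kPa.
#' @param signal_floor Minimum stiffness counted as signal, kPa.
#' @return Object of class `"class_ranges"`.
#' @export
class_ranges <- function(cancer_low = 520, cancer_high = 950,
                         cancer_max = 1418, stroma = c(92, 515),
                         signal_floor = 1) {
  if (!(0 < signal_floor && signal_floor < stroma[1] &&
        stroma[1] < stroma[2] && stroma[2] < cancer_low &&
        cancer_low < cancer_high && cancer_high <= cancer_max))
    coce_stop("class ranges must satisfy 0 < floor < stroma < cancer_low < cancer_high <= cancer_max")
  structure(list(cancer_low = cancer_low, cancer_high = cancer_high,
                 cancer_max = cancer_max, stroma = stroma,
                 signal_floor = signal_floor),
            class = "class_ranges")
}

#' Threshold segmentation of a stiffness map
#'
#' Assigns each pixel to exactly one morphological stiffness class using
#' half-open intervals (upper-exclusive except the top class):
#' `[signal_floor, stroma_min)` low-stiffness tissue,
#' `[stroma_min, cancer_low)` stroma, `[cancer_low, cancer_high]`
#' glandular cancer, `(cancer_high, Inf)` very high (non-glandular cancer).
#' Masked pixels and values below the signal floor are non-signal.
#'
#' @param map A `"coce_stiffness"` (or `"coce_fit"`).
#' @param ranges A [class_ranges()].
#' @return Object of class `"coce_classmap"`: integer class matrix with
#'   levels `NON_SIGNAL, LOW, STROMA, CANCER_GLAND, VERY_HIGH`, pixel sizes
#'   and the silicone row count.
#' @export
classify_pixels <- function(map, ranges = class_ranges()) {
  if (inherits(map, "coce_fit")) map <- map$stiffness
  stopifnot(inherits(map, "coce_stiffness"), inherits(ranges, "class_ranges"))
  v <- map$values
  cls <- matrix(CLASS_LEVELS[["NON_SIGNAL"]], nrow(v), ncol(v))
  ok <- map$signal_mask & is.finite(v)
  cls[ok & v >= ranges$signal_floor & v < ranges$stroma[1]] <- CLASS_LEVELS[["LOW"]]
  cls[ok & v >= ranges$stroma[1] & v < ranges$cancer_low] <- CLASS_LEVELS[["STROMA"]]
  cls[ok & v >= ranges$cancer_low & v <= ranges$cancer_high] <- CLASS_LEVELS[["CANCER_GLAND"]]
  cls[ok & v > ranges$cancer_high] <- CLASS_LEVELS[["VERY_HIGH"]]
  structure(
    list(classes = cls, axial_pixel_um = map$axial_pixel_um,
         lateral_pixel_um = map$lateral_pixel_um,
         silicone_px = map$silicone_px, ranges = ranges),
    class = "coce_classmap")
}

# 8-connected component labelling of a logical matrix via an igraph
# neighbour graph; returns an integer matrix (0 = background).
label_components <- function(mask) {
  D <- nrow(mask); W <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, D, W)
  if (length(idx) == 0) return(lab)
  vid <- matrix(0L, D, W)
  vid[idx] <- seq_along(idx)
  edges <- integer(0)
  offsets <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    r1 <- seq_len(D - dr)
    c1 <- if (dc >= 0) seq_len(W - dc) else seq.int(1L - dc, W)
    r2 <- r1 + dr; c2 <- c1 + dc
    both <- mask[r1, c1, drop = FALSE] & mask[r2, c2, drop = FALSE]
    if (any(both)) {
      from <- vid[r1, c1, drop = FALSE][both]
      to <- vid[r2, c2, drop = FALSE][both]
      edges <- c(edges, rbind(from, to))
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  lab[idx] <- igraph::components(g)$membership
  lab
}

#' Gland-like structure detection
#'
#' Finds 8-connected components of glandular-cancer pixels (520-950 kPa)
#' in the tissue region and decides whether the map shows "gland-like
#' structures": at least `min_components` discrete components of at least
#' `min_area_um2` each (one 110 x 110 um analysis ROI by default, the size
#' of a 7 x 7 speckle block), while glandular-cancer pixels cover less than
#' `max_coverage` of the signal area — discrete stiff nests in a softer
#' background rather than one contiguous stiff field.
#'
#' @param class_map A [classify_pixels()] result.
#' @param min_area_um2 Minimum component area, um^2 (default `110 * 110`).
#' @param min_components Minimum number of qualifying components
#'   (default 2).
#' @param max_coverage Maximum glandular-cancer fraction of the signal area
#'   (default 0.7).
#' @return List with `components` (data frame: id, n_px, area_um2) and
#'   `has_gland_like`.
#' @export
gland_like_components <- function(class_map, min_area_um2 = 110 * 110,
                                  min_components = 2L, max_coverage = 0.7) {
  stopifnot(inherits(class_map, "coce_classmap"))
  cls <- tissue_classes(class_map)
  px_area <- class_map$axial_pixel_um * class_map$lateral_pixel_um
  lab <- label_components(cls == CLASS_LEVELS[["CANCER_GLAND"]])
  sizes <- tabulate(lab)
  comp <- data.frame(id = seq_along(sizes), n_px = sizes,
                     area_um2 = sizes * px_area)
  comp <- comp[comp$area_um2 >= min_area_um2, , drop = FALSE]
  signal_px <- sum(cls != CLASS_LEVELS[["NON_SIGNAL"]])
  coverage <- if (signal_px > 0)
    sum(cls == CLASS_LEVELS[["CANCER_GLAND"]]) / signal_px else 0
  list(components = comp,
       has_gland_like = nrow(comp) >= min_components && coverage < max_coverage)
}

# tissue part of the class matrix (silicone rows removed)
tissue_classes <- function(class_map) {
  s <- class_map$silicone_px
  class_map$classes[seq.int(s + 1L, nrow(class_map$classes)), , drop = FALSE]
}

#' Non-signal area fraction near the tissue surface
#'
#' Fraction of non-signal pixels among all tissue pixels within
#' `depth_limit_um` of the silicone-tissue interface. The OCT signal
#' rarely penetrates deeper than ~500 um, so non-signal (mucin, wide gland
#' lumina) is quantified only in this superficial band; the fraction is
#' taken of the *total* band area, matching the "at least 50% of the total
#' tissue area" criterion for mucinous adenocarcinoma.
#'
#' @param class_map A [classify_pixels()] result.
#' @param depth_limit_um Counting depth below the interface, um.
#' @return Fraction in `[0, 1]`.
#' @export
nonsignal_fraction <- function(class_map, depth_limit_um = 500) {
  stopifnot(inherits(class_map, "coce_classmap"))
  cls <- tissue_classes(class_map)
  n <- min(nrow(cls), max(1L, round(depth_limit_um / class_map$axial_pixel_um)))
  if (nrow(cls) == 0 || n < 1) coce_stop("empty tissue ROI")
  band <- cls[seq_len(n), , drop = FALSE]
  mean(band == CLASS_LEVELS[["NON_SIGNAL"]])
}

#' Cancer area percentage of a segmented map
#'
#' Percentage of tissue-region pixels (silicone rows excluded) assigned to
#' a cancer class (glandular 520-950 kPa or very-high >950 kPa). Any area
#' above the 520 kPa threshold marks a sample as cancer-bearing.
#'
#' @param class_map A [classify_pixels()] result.
#' @return Percentage in `[0, 100]`.
#' @export
cancer_area_percent <- function(class_map) {
  stopifnot(inherits(class_map, "coce_classmap"))
  cls <- tissue_classes(class_map)
  100 * mean(cls %in% CLASS_LEVELS[c("CANCER_GLAND", "VERY_HIGH")])
}

#' Feature vector for subtype calling
#'
#' Extracts the stiffness-feature vector used by the subtype decision
#' table. Presence of a stiffness class requires at least one full
#' analysis ROI (`min_area_um2`, default 110 x 110 um) of contiguous
#' pixels of that class, so single speckle outliers do not flag a sample.
#'
#' @param class_map A [classify_pixels()] result.
#' @param min_area_um2 Contiguous-area requirement for class presence.
#' @param min_components,max_coverage Passed to [gland_like_components()].
#' @param depth_limit_um Passed to [nonsignal_fraction()].
#' @return List with `has_520_950`, `has_gt950`, `has_gland_like`,
#'   `nonsignal_fraction`.
#' @export
coce_features <- function(class_map, min_area_um2 = 110 * 110,
                          min_components = 2L, max_coverage = 0.7,
                          depth_limit_um = 500) {
  cls <- tissue_classes(class_map)
  px_area <- class_map$axial_pixel_um * class_map$lateral_pixel_um
  has_class <- function(level) {
    lab <- label_components(cls == CLASS_LEVELS[[level]])
    any(tabulate(lab) * px_area >= min_area_um2)
  }
  gl <- gland_like_components(class_map, min_area_um2, min_components,
                              max_coverage)
  list(has_520_950 = has_class("CANCER_GLAND"),
       has_gt950 = has_class("VERY_HIGH"),
       has_gland_like = gl$has_gland_like,
       nonsignal_fraction = nonsignal_fraction(class_map, depth_limit_um))
}

#' Morphological subtype decision
#'
#' Ordered decision table over the stiffness features, following the
#' characteristic C-OCE feature combinations of colorectal tumour
#' subtypes:
#' \itemize{
#'   \item no cancer-range stiffness at all: `NON_CANCEROUS` (stiffness
#'     alone cannot separate normal colon from benign adenoma);
#'   \item signal loss in at least half the tissue area: `MAC` (mucinous
#'     adenocarcinoma) when very-high stiffness is present without
#'     gland-like structures, otherwise `INDETERMINATE`;
#'   \item partial signal loss (above `loss_floor`, below one half) with
#'     gland-like structures and no very-high stiffness:
#'     `CRAC_CRIBRIFORM`;
#'   \item no loss, gland-like structures, no very-high stiffness:
#'     `LOW_GRADE_CRAC`;
#'   \item no loss, very-high stiffness, no gland-like structures:
#'     `HIGH_GRADE_CRAC`;
#'   \item anything else: `INDETERMINATE` (inconsistent feature
#'     combinations are never silently coerced).
#' }
#'
#' @param features Feature list from [coce_features()] (fields
#'   `has_520_950`, `has_gt950`, `has_gland_like`, `nonsignal_fraction`).
#' @param loss_floor Non-signal fraction below which signal loss is treated
#'   as absent (default 0.02, tolerating sporadic reconstruction dropouts).
#' @return Object of class `"coce_subtype"`: `call` (one of
#'   `r paste(SUBTYPE_CALLS, collapse = ", ")`) and the feature vector.
#' @export
subtype_call <- function(features, loss_floor = 0.02) {
  f <- features
  stopifnot(is.logical(f$has_520_950), is.logical(f$has_gt950),
            is.logical(f$has_gland_like),
            f$nonsignal_fraction >= 0, f$nonsignal_fraction <= 1)
  loss <- f$nonsignal_fraction
  call <- if (!f$has_520_950 && !f$has_gt950) {
    "NON_CANCEROUS"
  } else if (loss >= 0.5) {
    if (f$has_gt950 && !f$has_gland_like) "MAC" else "INDETERMINATE"
  } else if (loss > loss_floor) {
    if (f$has_gland_like && !f$has_gt950) "CRAC_CRIBRIFORM" else "INDETERMINATE"
  } else if (f$has_gland_like && !f$has_gt950) {
    "LOW_GRADE_CRAC"
  } else if (f$has_gt950 && !f$has_gland_like) {
    "HIGH_GRADE_CRAC"
  } else {
    "INDETERMINATE"
  }
  structure(list(call = call, features = f), class = "coce_subtype")
}

#' Segment a stiffness map and call the tumour subtype
#'
#' Chains [classify_pixels()], [coce_features()], [subtype_call()] and
#' [cancer_area_percent()].
#'
#' @param x A `"coce_stiffness"` or `"coce_fit"`.
#' @param config A [coce_config()] supplying thresholds; overridable via
#'   `...`.
#' @param ... Named config overrides.
#' @return Object of class `"coce_segmentation"` with `class_map`,
#'   `features`, `call` and `cancer_area_percent`.
#' @export
coce_segment <- function(x, config = coce_config(), ...) {
  if (inherits(x, "coce_fit")) x <- x$stiffness
  config <- modify_config(config, ...)
  cm <- classify_pixels(x, config$class_ranges)
  feats <- coce_features(cm,
                         min_area_um2 = config$min_gland_area_um2,
                         min_components = config$gland_min_components,
                         max_coverage = config$gland_max_coverage,
                         depth_limit_um = config$depth_limit_um)
  call <- subtype_call(feats, loss_floor = config$loss_floor)
  structure(
    list(class_map = cm, features = feats, call = call$call,
         cancer_area_percent = cancer_area_percent(cm)),
    class = "coce_segmentation")
}

#' @export
print.coce_segmentation <- function(x, ...) {
  cat(sprintf("C-OCE segmentation: subtype call %s\n", x$call))
  f <- x$features
  cat(sprintf("  520-950 kPa: %s | >950 kPa: %s | gland-like: %s | signal loss: %.1f%%\n",
              f$has_520_950, f$has_gt950, f$has_gland_like,
              100 * f$nonsignal_fraction))
  cat(sprintf("  cancer area: %.1f%% of tissue\n", x$cancer_area_percent))
  tab <- table(factor(tissue_classes(x$class_map),
                      levels = CLASS_LEVELS, labels = names(CLASS_LEVELS)))
  cat("  class areas (% of tissue):",
      paste(sprintf("%s %.1f", names(tab), 100 * tab / sum(tab)),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.coce_subtype <- function(x, ...) {
  cat("Subtype call:", x$call, "\n")
  invisible(x)
}
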