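#' Pearson correlation with significance
#'
#' Product-moment correlation between two paired samples; the p-value comes
#' from the t transform \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on `n - 2` degrees
#' of freedom (two-sided), as computed by [stats::cor.test()].
#'
#' @param x,y Numeric vectors of equal length (>= 3), non-constant.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) coce_stop("x and y must be paired")
  if (length(x) < 3) coce_stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    coce_stop("constant input: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Bland-Altman method agreement
#'
#' Differences `measured - reference` summarized as the bias (mean
#' difference), the sample standard deviation of the differences, and the
#' 95% limits of agreement `bias +/- 1.96 sd` (set `exact_t = TRUE` for the
#' small-sample t multiplier).
#'
#' @param measured,reference Paired numeric vectors (>= 3 pairs).
#' @param exact_t Use `qt(0.975, n - 1)` instead of 1.96.
#' @return Object of class `"bland_altman"`: `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `n`, plus per-pair `means` and `diffs` for plotting.
#' @export
bland_altman <- function(measured, reference, exact_t = FALSE) {
  if (length(measured) != length(reference))
    coce_stop("measured and reference must be paired")
  if (length(measured) < 3) coce_stop("need at least 3 pairs")
  d <- measured - reference
  bias <- mean(d)
  sdd <- stats::sd(d)
  mult <- if (exact_t) stats::qt(0.975, length(d) - 1) else 1.96
  structure(
    list(bias = bias, sd_diff = sdd,
         loa_low = bias - mult * sdd, loa_high = bias + mult * sdd,
         n = length(d), means = (measured + reference) / 2, diffs = d),
    class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement (n = %d): bias %.3f, 95%% LoA [%.3f; %.3f]\n",
              x$n, x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' Bland-Altman plot
#'
#' @param x A [bland_altman()] result.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$diffs, pch = 19,
                 xlab = "mean of methods", ylab = "difference", ...)
  graphics::abline(h = c(x$bias, x$loa_low, x$loa_high),
                   lty = c(2, 3, 3), col = "blue")
  invisible(x)
}

#' One-tailed two-sample Student's t-test
#'
#' Classical pooled-variance t-test with a one-tailed alternative.
#' `alternative = "greater"` tests whether the mean of `a` exceeds the mean
#' of `b`. When both groups are degenerate (zero variance): equal means
#' give `p = 0.5` by convention (flagged with a warning); unequal means
#' give `p = 0` or `1` according to the observed direction. Welch's
#' correction is available behind `var_equal = FALSE`.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param alternative `"greater"` or `"less"` (mean(a) vs mean(b)).
#' @param var_equal Pooled variance (classical Student) when `TRUE`
#'   (default).
#' @return List with `p`, `t`, `df`.
#' @export
t_test_one_tailed <- function(a, b, alternative = c("greater", "less"),
                              var_equal = TRUE) {
  alternative <- match.arg(alternative)
  if (length(a) < 2 || length(b) < 2)
    coce_stop("each group needs at least 2 observations")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      warning("degenerate variance with equal means: p = 0.5 by convention")
      return(list(p = 0.5, t = 0, df = length(a) + length(b) - 2))
    }
    obs_greater <- mean(a) > mean(b)
    p <- if ((alternative == "greater") == obs_greater) 0 else 1
    return(list(p = p, t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2))
  }
  tt <- stats::t.test(a, b, alternative = alternative, var.equal = var_equal)
  list(p = tt$p.value, t = unname(tt$statistic), df = unname(tt$parameter))
}

#' Summary statistic in the package's reporting format
#'
#' Mean, sample standard deviation and range, formatted as
#' `"mean +/- sd [min; max]"` — the style used for all stiffness
#' statistics in this package.
#'
#' @param values Numeric vector (>= 1 value).
#' @param digits Significant digits for the formatted text.
#' @return Object of class `"summary_stat"`: `mean`, `sd`, `min`, `max`,
#'   `n`, `text`.
#' @export
summarize_stat <- function(values, digits = 3) {
  if (length(values) == 0) coce_stop("no values to summarize")
  m <- mean(values)
  s <- if (length(values) > 1) stats::sd(values) else 0
  fmt <- function(v) format(signif(v, digits), trim = TRUE, scientific = FALSE)
  structure(
    list(mean = m, sd = s, min = min(values), max = max(values),
         n = length(values),
         text = sprintf("%s ± %s [%s; %s]", fmt(m), fmt(s),
                        fmt(min(values)), fmt(max(values)))),
    class = "summary_stat")
}

#' @export
print.summary_stat <- function(x, ...) {
  cat(x$text, "\n")
  invisible(x)
}

#' Morphometric agreement experiment
#'
#' Compares cancer-area percentages measured by C-OCE segmentation with
#' reference (ground-truth or histology-style) percentages across a cohort:
#' per-sample table, Pearson correlation, and Bland-Altman bias with 95%
#' limits of agreement. Optionally writes the per-sample CSV, a JSON stats
#' report, and scatter / Bland-Altman plots.
#'
#' @param coce_percent Numeric vector of segmented cancer-area
#'   percentages.
#' @param truth_percent Paired reference percentages.
#' @param sample_id Optional ids (default `S1..Sn`).
#' @param out_dir Optional output directory for `samples.csv`,
#'   `agreement.json`, `scatter.png`, `bland_altman.png`.
#' @return Object of class `"coce_agreement"`: `table` (data frame),
#'   `pearson`, `bland_altman`.
#' @export
run_agreement_experiment <- function(coce_percent, truth_percent,
                                     sample_id = NULL, out_dir = NULL) {
  if (length(coce_percent) != length(truth_percent))
    coce_stop("unpaired inputs: %d C-OCE vs %d reference values",
              length(coce_percent), length(truth_percent))
  if (is.null(sample_id)) sample_id <- paste0("S", seq_along(coce_percent))
  tab <- data.frame(sample_id = sample_id,
                    truth_percent = truth_percent,
                    coce_percent = coce_percent,
                    diff = coce_percent - truth_percent)
  pe <- pearson_r(coce_percent, truth_percent)
  ba <- bland_altman(coce_percent, truth_percent)
  out <- structure(list(table = tab, pearson = pe, bland_altman = ba),
                   class = "coce_agreement")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tab, file.path(out_dir, "samples.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(pearson = pe,
           bland_altman = ba[c("bias", "sd_diff", "loa_low", "loa_high", "n")]),
      file.path(out_dir, "agreement.json"), auto_unbox = TRUE, digits = NA)
    grDevices::png(file.path(out_dir, "scatter.png"), 600, 600)
    graphics::plot(truth_percent, coce_percent, pch = 19,
                   xlab = "reference cancer area, %",
                   ylab = "C-OCE cancer area, %")
    graphics::abline(0, 1, lty = 2)
    grDevices::dev.off()
    grDevices::png(file.path(out_dir, "bland_altman.png"), 600, 600)
    plot(ba)
    grDevices::dev.off()
  }
  out
}

#' @export
print.coce_agreement <- function(x, ...) {
  cat(sprintf("Agreement over %d samples: Pearson r = %.4f (p = %.3g)\n",
              x$pearson$n, x$pearson$r, x$pearson$p))
  print(x$bland_altman)
  invisible(x)
}
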