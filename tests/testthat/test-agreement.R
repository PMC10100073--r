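test_that("pearson_r reproduces exact and hand-computed correlations", {
  expect_equal(pearson_r(1:4, c(2, 4, 6, 8))$r, 1)
  expect_equal(pearson_r(1:4, c(4, 3, 2, 1))$r, -1)
  x <- c(10, 20, 30, 40, 50); y <- c(12, 19, 33, 38, 52)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y)$r, r_hand, tolerance = 1e-15)
  expect_error(pearson_r(rep(1, 5), 1:5), "constant")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("pearson and bland_altman match brute-force formulas to 1e-12", {
  set.seed(13)
  for (k in 1:1000) {
    n <- sample(3:40, 1)
    x <- rnorm(n); y <- x * runif(1, 0.5, 2) + rnorm(n)
    if (sd(y) == 0) next
    r_hand <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    pe <- pearson_r(x, y)
    expect_lt(abs(pe$r - r_hand), 1e-12)
    t_hand <- r_hand * sqrt((n - 2) / (1 - r_hand^2))
    p_hand <- 2 * stats::pt(-abs(t_hand), n - 2)
    expect_lt(abs(pe$p - p_hand), 1e-12)
    ba <- bland_altman(x, y)
    d <- x - y
    expect_lt(abs(ba$bias - mean(d)), 1e-12)
    expect_lt(abs(ba$sd_diff - sqrt(sum((d - mean(d))^2) / (n - 1))), 1e-12)
    expect_lt(abs(ba$loa_high - (mean(d) + 1.96 * sd(d))), 1e-12)
  }
})

test_that("bland_altman handles the textbook special cases", {
  x <- c(1, 2, 3)
  ba <- bland_altman(x, x)
  expect_equal(c(ba$bias, ba$loa_low, ba$loa_high), c(0, 0, 0))
  ba2 <- bland_altman(x + 2, x)
  expect_equal(c(ba2$bias, ba2$loa_low, ba2$loa_high), c(2, 2, 2))
  ba3 <- bland_altman(c(-1, 0, 1) + x, x)
  expect_equal(ba3$bias, 0)
  expect_equal(ba3$sd_diff, 1)
  expect_equal(c(ba3$loa_low, ba3$loa_high), c(-1.96, 1.96))
  expect_error(bland_altman(1:4, 1:3), "paired")
})

test_that("bland_altman bias is antisymmetric in its arguments", {
  set.seed(17)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(bland_altman(a, b)$bias, -bland_altman(b, a)$bias)
})

test_that("pearson is invariant under positive affine maps", {
  set.seed(19)
  x <- rnorm(25); y <- 2 * x + rnorm(25)
  r0 <- pearson_r(x, y)$r
  expect_equal(pearson_r(3 * x + 7, y)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_r(x, 0.1 * y - 4)$r, r0, tolerance = 1e-12)
})

test_that("one-tailed pooled t-test matches a hand computation", {
  a <- c(1, 2, 3); b <- c(11, 12, 13)
  res <- t_test_one_tailed(a, b, alternative = "less")
  sp <- sqrt((2 * var(a) + 2 * var(b)) / 4)
  t_hand <- (mean(a) - mean(b)) / (sp * sqrt(2 / 3))
  expect_equal(res$t, t_hand)       # -12.24745
  expect_equal(res$p, stats::pt(t_hand, 4))
  expect_lt(res$p, 0.001)
  # wrong direction: nowhere near significant
  expect_gt(t_test_one_tailed(a, b, alternative = "greater")$p, 0.99)
})

test_that("degenerate-variance groups are flagged with the p = 0.5 convention", {
  expect_warning(res <- t_test_one_tailed(c(5, 5), c(5, 5)), "convention")
  expect_equal(res$p, 0.5)
  expect_equal(t_test_one_tailed(c(6, 6), c(5, 5), "greater")$p, 0)
  expect_equal(t_test_one_tailed(c(6, 6), c(5, 5), "less")$p, 1)
})

test_that("adenoma is not significantly stiffer than mucosa at the printed spread", {
  # class distributions: adenoma 46 +/- 22 kPa, mucosa 58 +/- 28 kPa
  set.seed(23)
  adenoma <- rnorm(30, 46, 22)
  mucosa <- rnorm(30, 58, 28)
  p <- t_test_one_tailed(adenoma, mucosa, alternative = "greater")$p
  expect_gt(p, 0.05)
})

test_that("summary statistics print in the mean +/- sd [min; max] house style", {
  s <- summarize_stat(c(5, 5, 5))
  expect_equal(s$text, "5 ± 0 [5; 5]")
  s2 <- summarize_stat(c(2, 4, 6))
  expect_equal(s2$mean, 4)
  expect_equal(s2$sd, 2)
  expect_equal(s2$text, "4 ± 2 [2; 6]")
  s3 <- summarize_stat(c(23, 104, 47))
  expect_match(s3$text, "\\[23; 104\\]")
  expect_error(summarize_stat(numeric(0)), "no values")
})

test_that("the agreement experiment reproduces its own inputs and files", {
  # perfect agreement
  p <- c(10, 30, 50, 70)
  self <- run_agreement_experiment(p, p)
  expect_equal(self$pearson$r, 1)
  expect_equal(self$bland_altman$bias, 0)

  # seeded noise: stats recomputable from the emitted CSV
  set.seed(29)
  meas <- p + runif(4, -2, 2)
  dir <- tempfile("agree")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  res <- run_agreement_experiment(meas, p, out_dir = dir)
  tab <- read.csv(file.path(dir, "samples.csv"))
  expect_equal(tab$coce_percent, meas)
  re <- pearson_r(tab$coce_percent, tab$truth_percent)
  expect_equal(re$r, res$pearson$r)
  ba <- bland_altman(tab$coce_percent, tab$truth_percent)
  expect_equal(ba$loa_low, res$bland_altman$loa_low)
  expect_true(file.exists(file.path(dir, "agreement.json")))
  expect_true(file.exists(file.path(dir, "bland_altman.png")))
  expect_error(run_agreement_experiment(1:3, 1:4), "unpaired")
})
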