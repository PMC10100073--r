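sweep_map <- function(values, ...) {
  stiffness_map(matrix(values, nrow = 1), mask = matrix(TRUE, 1,
                length(values)), ...)
}

test_that("class boundaries sit exactly at the published thresholds", {
  vals <- 0:1500
  cm <- classify_pixels(sweep_map(vals))
  cls <- as.vector(cm$classes)
  expect_equal(min(vals[cls %in% c(3, 4)]), 520)
  expect_equal(max(vals[cls == 3]), 950)
  expect_equal(min(vals[cls == 4]), 951)
  expect_equal(min(vals[cls == 2]), 92)
  expect_equal(min(vals[cls == 1]), 1)
  expect_equal(vals[cls == 0], 0)          # below the 1 kPa signal floor
  # the printed 515-520 kPa gap belongs to stroma
  expect_true(all(cls[vals %in% 515:519] == 2))
  # representative class means land in their classes
  expect_equal(cls[vals == 724], 3)
  expect_equal(cls[vals == 954], 4)
})

test_that("masked pixels are non-signal and the classes partition the map", {
  v <- matrix(runif(600, 0, 1500), 20, 30)
  mask <- matrix(runif(600) > 0.3, 20, 30)
  cm <- classify_pixels(stiffness_map(v, mask))
  expect_true(all(cm$classes[!mask] == 0))
  counts <- table(factor(cm$classes, levels = 0:4))
  expect_equal(sum(counts), 600)
  # every pixel has exactly one class by construction of the int matrix
  expect_true(all(cm$classes %in% 0:4))
})

test_that("invalid threshold orderings are rejected", {
  expect_error(class_ranges(cancer_low = 90), "class ranges")
  expect_error(class_ranges(signal_floor = 0), "class ranges")
})

test_that("connected components match a flood-fill oracle", {
  set.seed(11)
  for (rep in 1:5) {
    m <- matrix(runif(30 * 40) < 0.35, 30, 40)
    got <- coce:::label_components(m)
    want <- flood_label(m)
    # same partition: label images agree up to renaming
    expect_equal(max(got), max(want))
    key <- paste(got[m], want[m])
    expect_equal(length(unique(key)), max(want))
  }
})

test_that("gland-like structures mean discrete nests, not a solid field", {
  mk <- function(cls) {
    structure(list(classes = cls, axial_pixel_um = 10, lateral_pixel_um = 10,
                   silicone_px = 0L, ranges = class_ranges()),
              class = "coce_classmap")
  }
  # all stroma: no components
  all_stroma <- mk(matrix(2L, 60, 60))
  expect_false(gland_like_components(all_stroma)$has_gland_like)
  expect_equal(nrow(gland_like_components(all_stroma)$components), 0)

  # two 200 x 200 um squares (20 x 20 px at 10 um) in stroma
  cls <- matrix(2L, 60, 60)
  cls[10:29, 10:29] <- 3L
  cls[35:54, 35:54] <- 3L
  two <- gland_like_components(mk(cls))
  expect_equal(nrow(two$components), 2)
  expect_true(two$has_gland_like)
  expect_equal(sort(two$components$n_px), c(400, 400))

  # one solid glandular field covering the ROI is not gland-like
  solid <- mk(matrix(3L, 60, 60))
  expect_false(gland_like_components(solid)$has_gland_like)

  # sub-ROI speckle outliers do not count
  cls <- matrix(2L, 60, 60)
  cls[5, 5] <- 3L; cls[40, 40] <- 3L
  expect_false(gland_like_components(mk(cls))$has_gland_like)
})

test_that("non-signal fraction counts the superficial band only", {
  # 100 x 100 px at 10 um: depth limit 500 um = top 50 tissue rows
  cls <- matrix(2L, 100, 100)
  cls[1:30, ] <- 0L  # 30-row non-signal band within the limit
  cm <- structure(list(classes = cls, axial_pixel_um = 10,
                       lateral_pixel_um = 10, silicone_px = 0L),
                  class = "coce_classmap")
  expect_equal(nonsignal_fraction(cm, depth_limit_um = 500), 30 / 50)
  expect_equal(nonsignal_fraction(cm, depth_limit_um = 1000), 0.30)
  # fully signalled ROI
  cm$classes[] <- 2L
  expect_equal(nonsignal_fraction(cm), 0)
  # measured from the silicone-tissue interface, not the image top
  cls2 <- rbind(matrix(0L, 20, 100), matrix(2L, 80, 100))
  cls2[21:30, ] <- 0L
  cm2 <- structure(list(classes = cls2, axial_pixel_um = 10,
                        lateral_pixel_um = 10, silicone_px = 20L),
                   class = "coce_classmap")
  expect_equal(nonsignal_fraction(cm2, depth_limit_um = 500), 10 / 50)
})

test_that("cancer area percentage counts cancer classes in tissue", {
  cls <- matrix(2L, 40, 50)
  cls[1:20, ] <- 3L
  cm <- structure(list(classes = cls, axial_pixel_um = 10,
                       lateral_pixel_um = 10, silicone_px = 0L),
                  class = "coce_classmap")
  expect_equal(cancer_area_percent(cm), 50)
  cm$classes[1:10, ] <- 4L  # very-high counts as cancer too
  expect_equal(cancer_area_percent(cm), 50)
  cm$classes[] <- 2L
  expect_equal(cancer_area_percent(cm), 0)
})

test_that("subtype decisions match the Table-2 truth table exhaustively", {
  combos <- expand.grid(h520 = c(FALSE, TRUE), h950 = c(FALSE, TRUE),
                        gl = c(FALSE, TRUE),
                        loss = c(0, 0.01, 0.1, 0.3, 0.49, 0.5, 0.6, 1))
  for (k in seq_len(nrow(combos))) {
    cb <- combos[k, ]
    got <- subtype_call(list(has_520_950 = cb$h520, has_gt950 = cb$h950,
                             has_gland_like = cb$gl,
                             nonsignal_fraction = cb$loss))$call
    expect_equal(got, subtype_oracle(cb$h520, cb$h950, cb$gl, cb$loss),
                 info = paste(unlist(cb), collapse = " "))
  }
})

test_that("canonical subtype feature combinations give the expected calls", {
  f <- function(h520, h950, gl, loss)
    subtype_call(list(has_520_950 = h520, has_gt950 = h950,
                      has_gland_like = gl, nonsignal_fraction = loss))$call
  expect_equal(f(TRUE, FALSE, TRUE, 0), "LOW_GRADE_CRAC")
  expect_equal(f(TRUE, TRUE, FALSE, 0), "HIGH_GRADE_CRAC")
  expect_equal(f(FALSE, FALSE, FALSE, 0), "NON_CANCEROUS")
  expect_equal(f(TRUE, TRUE, FALSE, 0.6), "MAC")
  expect_equal(f(TRUE, FALSE, TRUE, 0.3), "CRAC_CRIBRIFORM")
  # conflicting combinations are never coerced
  expect_equal(f(TRUE, TRUE, TRUE, 0.6), "INDETERMINATE")
  expect_equal(f(TRUE, FALSE, TRUE, 0.6), "INDETERMINATE")
})

test_that("the MAC switch point sits at half the tissue area", {
  calls <- vapply(seq(0, 1, by = 0.01), function(loss)
    subtype_call(list(has_520_950 = TRUE, has_gt950 = TRUE,
                      has_gland_like = FALSE,
                      nonsignal_fraction = loss))$call, character(1))
  expect_equal(min(which(calls == "MAC")), 51)  # loss = 0.50
  expect_equal(calls[50], "INDETERMINATE")      # loss = 0.49, gt950, no glands
})
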