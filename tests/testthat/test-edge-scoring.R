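test_that("normalization divides by 255 and rejects out-of-range input", {
  em <- normalize_edge_map(matrix(c(255, 0, 51, 102), 2, 2))
  expect_equal(sort(as.vector(em$values)), c(0, 0.2, 0.4, 1))
  expect_equal(em$size, image_size(2, 2))
  expect_error(normalize_edge_map(matrix(c(-1, 0, 0, 0), 2, 2)), "\\[0, 255\\]")
  expect_error(normalize_edge_map(matrix(256, 1, 1)), "\\[0, 255\\]")
})

test_that("a symmetric two-delta histogram thresholds at 0.5", {
  em <- normalize_edge_map(matrix(c(rep(0, 50), rep(255, 50)), 10, 10))
  expect_equal(intermode_threshold(em), 127.5 / 255)
})

test_that("intermode matches a loop-based reimplementation on random bimodal histograms", {
  set.seed(21)
  for (i in 1:100) {
    counts <- integer(256)
    m1 <- sample(10:90, 1); m2 <- sample(140:240, 1)
    b1 <- round(rnorm(400, m1, sample(3:12, 1)))
    b2 <- round(rnorm(sample(c(200, 400, 700), 1), m2, sample(3:12, 1)))
    for (v in c(b1, b2)) if (v >= 0 && v <= 255)
      counts[v + 1] <- counts[v + 1] + 1L
    em <- em_from_histogram(counts)
    expected <- bf_intermodes(counts)
    if (is.na(expected)) {
      expect_warning(intermode_threshold(em), "bimodality")
    } else {
      expect_equal(intermode_threshold(em), expected, tolerance = 1e-12)
    }
  }
})

test_that("a constant map falls back to the histogram mean with a warning", {
  em <- normalize_edge_map(matrix(102, 5, 5))
  expect_warning(thr <- intermode_threshold(em), "bimodality")
  expect_equal(thr, 0.4)
})

test_that("binarization is a strict > comparison with the threshold recorded", {
  z <- normalize_edge_map(matrix(0, 4, 4))
  expect_true(all(binarize_edge_map(z, 0)$values == 0))
  ones <- normalize_edge_map(matrix(255, 4, 4))
  expect_true(all(binarize_edge_map(ones, 0.5)$values == 1))
  set.seed(22)
  raw <- matrix(sample(0:255, 16), 4, 4)
  em <- normalize_edge_map(raw)
  bem <- binarize_edge_map(em, 0.5)
  expect_equal(bem$values, (raw / 255 > 0.5) + 0)
  expect_equal(bem$threshold_used, 0.5)
  expect_error(binarize_edge_map(em, 1.5), "\\[0, 1\\]")
})

test_that("S is the edge-intensity sum over the box", {
  ones <- normalize_edge_map(matrix(255, 6, 6))
  expect_equal(indicator_S(ones, make_box(1, 1, 3, 3)), 9)
  expect_equal(indicator_S(normalize_edge_map(matrix(0, 6, 6)),
                           make_box(0, 0, 5, 5)), 0)
  raw <- matrix(c(10, 20, 30, 40, 50, 60, 70, 80,
                  90, 100, 110, 120, 130, 140, 150, 160), 4, 4)
  em <- normalize_edge_map(raw)
  roi <- make_box(1, 1, 2, 2)
  expect_equal(indicator_S(em, roi), (60 + 100 + 70 + 110) / 255)
  expect_error(indicator_S(em, make_box(0, 0, 4, 4)), "outside")
})

test_that("S and D match brute-force double loops on random maps and boxes", {
  set.seed(23)
  for (i in 1:60) {
    raw <- matrix(sample(0:255, 12 * 10, replace = TRUE), 10, 12)
    em <- normalize_edge_map(raw)
    bem <- binarize_edge_map(em, runif(1))
    roi <- random_box(12, 10)
    expect_equal(indicator_S(em, roi), bf_sum_in_box(em$values, roi),
                 tolerance = 1e-9)
    expect_equal(indicator_D(bem, roi),
                 bf_sum_in_box(bem$values, roi) / box_area(roi),
                 tolerance = 1e-9)
    expect_gte(indicator_D(bem, roi), 0)
    expect_lte(indicator_D(bem, roi), 1)
  }
})

test_that("D over the full frame equals the global set-pixel fraction", {
  set.seed(24)
  raw <- matrix(sample(0:255, 30 * 20, replace = TRUE), 20, 30)
  bem <- binarize_edge_map(normalize_edge_map(raw), 0.5)
  expect_equal(indicator_D(bem, make_box(0, 0, 29, 19)), mean(bem$values))
})

test_that("enlarging a box never decreases S; a box of only set pixels has D = 1", {
  set.seed(25)
  raw <- matrix(sample(0:255, 20 * 20, replace = TRUE), 20, 20)
  em <- normalize_edge_map(raw)
  for (i in 1:20) {
    inner <- make_box(5, 5, 10, 10)
    outer <- make_box(sample(0:5, 1), sample(0:5, 1),
                      sample(10:19, 1), sample(10:19, 1))
    expect_gte(indicator_S(em, outer), indicator_S(em, inner))
  }
  bem <- binarize_edge_map(normalize_edge_map(matrix(255, 5, 5)), 0.5)
  expect_equal(indicator_D(bem, make_box(1, 1, 3, 3)), 1)
})

test_that("SD is the exact product and scales linearly in the edge intensities", {
  sc <- roi_score(5507, 0.25)
  expect_identical(sc$SD, 5507 * 0.25)
  expect_equal(roi_score(0, 0.7)$SD, 0)
  set.seed(26)
  raw <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
  em <- normalize_edge_map(raw)
  bem <- binarize_edge_map(em, 0.5)
  roi <- make_box(2, 3, 7, 8)
  full <- score_roi(em, bem, roi)
  for (c in c(0.25, 0.5, 0.9)) {
    scaled <- normalize_edge_map(raw * c)
    sc2 <- score_roi(scaled, bem, roi)
    expect_equal(sc2$S, c * full$S, tolerance = 1e-12)
    expect_equal(sc2$D, full$D) # bem fixed, density unchanged
  }
  bad <- binarize_edge_map(normalize_edge_map(matrix(0, 4, 4)), 0.5)
  expect_error(score_roi(em, bad, roi), "differ in size")
})
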