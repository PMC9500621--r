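test_that("the same config yields a bit-identical phantom", {
  cfg <- small_phantom_config(7)
  p1 <- generate_phantom(cfg)
  p2 <- generate_phantom(cfg)
  expect_identical(p1$edge_raw, p2$edge_raw)
  expect_identical(p1$gold, p2$gold)
})

test_that("without clutter and noise only the boundary band is lit, and gold is its bounding box", {
  cfg <- phantom_config(width = 200, height = 160, center = c(100, 80),
                        semi_axes = c(50, 35), clutter_density = 0,
                        noise_sd = 0, seed = 3)
  ph <- generate_phantom(cfg)
  lit <- which(ph$edge_raw > 0, arr.ind = TRUE)
  expect_gt(nrow(lit), 0)
  expect_equal(ph$gold$x_min, min(lit[, 2]) - 1L)
  expect_equal(ph$gold$x_max, max(lit[, 2]) - 1L)
  expect_equal(ph$gold$y_min, min(lit[, 1]) - 1L)
  expect_equal(ph$gold$y_max, max(lit[, 1]) - 1L)
  # analytic extent: ellipse +/- half band width around the center
  hw <- cfg$boundary_width / (2 * min(cfg$semi_axes)) # normalized half width
  expect_lte(abs((100 - 50 * (1 + hw)) - ph$gold$x_min), 1.5)
  expect_lte(abs((100 + 50 * (1 + hw)) - ph$gold$x_max), 1.5)
})

test_that("edge density concentrates inside the gold box", {
  cfg <- small_phantom_config(9)
  ph <- generate_phantom(cfg)
  bem <- binarize_edge_map(ph$edge_map, intermode_threshold(ph$edge_map))
  frame_box <- make_box(0, 0, cfg$width - 1, cfg$height - 1)
  expect_gt(indicator_D(bem, ph$gold), 3 * indicator_D(bem, frame_box))
})

test_that("ellipse configurations that spill out of the frame are rejected", {
  expect_error(phantom_config(width = 100, height = 100, center = c(90, 50),
                              semi_axes = c(20, 20)), "fit inside")
})

test_that("hypothetical boxes reproduce the 50/25/75 percent area relations", {
  gold <- make_box(10, 20, 129, 99) # 120 x 80
  frame <- image_size(546, 479)
  r <- make_hypothetical_rois(gold, frame)
  ag <- box_area(gold)
  expect_equal(round(100 * (1 - box_area(r$roi1) / ag)), 50)
  expect_equal(round(100 * (box_area(r$roi2) / ag - 1)), 25)
  expect_equal(round(100 * (box_area(r$roi3) / ag - 1)), 75)
  # containment: roi1 inside gold; gold inside roi2 and roi3
  expect_equal(intersect_boxes(gold, r$roi1), r$roi1)
  expect_equal(intersect_boxes(gold, r$roi2), gold)
  expect_equal(intersect_boxes(gold, r$roi3), gold)
  # a gold box too close to the frame edge cannot host the +75% super-box
  expect_error(make_hypothetical_rois(make_box(0, 0, 119, 79),
                                      image_size(121, 81)), "cannot fit")
})

test_that("hypothetical areas stay on target across random gold boxes", {
  set.seed(71)
  frame <- image_size(546, 479)
  for (i in 1:25) {
    w <- sample(60:180, 1); h <- sample(50:140, 1)
    x <- sample(120:200, 1); y <- sample(120:180, 1)
    gold <- make_box(x, y, x + w - 1, y + h - 1)
    r <- make_hypothetical_rois(gold, frame)
    ag <- box_area(gold)
    expect_equal(round(100 * (1 - box_area(r$roi1) / ag)), 50)
    expect_equal(round(100 * (box_area(r$roi2) / ag - 1)), 25)
    expect_equal(round(100 * (box_area(r$roi3) / ag - 1)), 75)
  }
})

test_that("simulated detections are exact in the noiseless limit and absent at failure 1", {
  gold <- make_box(40, 30, 119, 89)
  frame <- image_size(200, 150)
  exact <- detector_sim_config(list(
    m1 = list(jitter_sd = 0, scale_bias = 1, failure_prob = 0),
    m2 = list(jitter_sd = 0, scale_bias = 1, failure_prob = 0)), seed = 5)
  cs <- simulate_detections(gold, frame, exact)
  expect_equal(cs$boxes$m1, gold)
  expect_equal(cs$boxes$m2, gold)
  never <- detector_sim_config(list(
    m1 = list(jitter_sd = 0, scale_bias = 1, failure_prob = 1)), seed = 5)
  expect_length(present_boxes <- Filter(Negate(is.null),
    simulate_detections(gold, frame, never)$boxes), 0)
})

test_that("corner jitter is unbiased (Monte Carlo)", {
  gold <- make_box(100, 100, 219, 199)
  frame <- image_size(400, 400)
  sd_px <- 5
  disp <- matrix(NA_real_, 1000, 4)
  for (i in 1:1000) {
    cfg <- detector_sim_config(list(
      m = list(jitter_sd = sd_px, scale_bias = 1, failure_prob = 0)),
      seed = 1000L + i)
    b <- simulate_detections(gold, frame, cfg)$boxes$m
    disp[i, ] <- unlist(b) - unlist(gold)
  }
  se <- sd_px / sqrt(1000)
  for (k in 1:4)
    expect_lte(abs(mean(disp[, k])), 3 * se + 0.5) # 0.5 for rounding
})

test_that("selection prefers the moderately enlarged hypothetical box on phantoms", {
  wins <- 0L
  n <- 200L
  for (i in seq_len(n)) {
    cfg <- small_phantom_config(5000 + i)
    ph <- generate_phantom(cfg)
    rois <- make_hypothetical_rois(ph$gold, ph$edge_map$size)
    sel <- select_roi(ph$edge_map, candidate_set("p", rois))
    if (sel$selected_model == "roi2") wins <- wins + 1L
  }
  expect_gte(wins / n, 0.9)
})

test_that("an unbiased detector among biased ones is selected more often than chance", {
  n <- 300L
  picks <- character(n)
  models <- list(
    over = list(jitter_sd = 4, scale_bias = 1.2, failure_prob = 0),
    under = list(jitter_sd = 4, scale_bias = 0.8, failure_prob = 0),
    unbiased = list(jitter_sd = 4, scale_bias = 1.0, failure_prob = 0),
    big = list(jitter_sd = 4, scale_bias = 1.3, failure_prob = 0))
  for (i in seq_len(n)) {
    cfg <- small_phantom_config(9000 + i)
    ph <- generate_phantom(cfg)
    cands <- simulate_detections(ph$gold, ph$edge_map$size,
                                 detector_sim_config(models, seed = 9000L + i))
    picks[i] <- select_roi(ph$edge_map, cands)$selected_model
  }
  n_unbiased <- sum(picks == "unbiased")
  bt <- stats::binom.test(n_unbiased, n, p = 1 / length(models),
                          alternative = "greater")
  expect_lt(bt$p.value, 0.01)
})
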