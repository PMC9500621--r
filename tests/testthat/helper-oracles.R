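# Brute-force pixel-level oracles, kept deliberately naive and independent
# of the package's vectorized implementations.

# enumerate the pixels of a box as a set of "x,y" strings
bf_pixels <- function(b) {
  out <- character(0)
  for (x in b$x_min:b$x_max)
    for (y in b$y_min:b$y_max)
      out <- c(out, paste(x, y))
  out
}

bf_overlap_count <- function(a, b) length(intersect(bf_pixels(a), bf_pixels(b)))

# rasterize a box into a logical mask over a width x height frame
bf_mask <- function(b, width, height) {
  m <- matrix(FALSE, height, width)
  m[(b$y_min + 1):(b$y_max + 1), (b$x_min + 1):(b$x_max + 1)] <- TRUE
  m
}

bf_sum_in_box <- function(values, b) {
  s <- 0
  for (j in (b$y_min + 1):(b$y_max + 1))
    for (i in (b$x_min + 1):(b$x_max + 1))
      s <- s + values[j, i]
  s
}

bf_metrics <- function(gold, pred, width, height) {
  g <- bf_mask(gold, width, height); p <- bf_mask(pred, width, height)
  ov <- sum(g & p)
  prec <- ov / sum(p); rec <- ov / sum(g)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  c(precision = prec, recall = rec, f1 = f1)
}

# independent loop-based intermodes: 3-bin moving average (zero-padded) until
# exactly two strict local maxima; midpoint of the mode bins / 255
bf_intermodes <- function(h, max_iter = 10000) {
  h <- as.numeric(h)
  for (it in seq_len(max_iter)) {
    peaks <- integer(0)
    for (k in seq_along(h)) {
      left <- if (k == 1) 0 else h[k - 1]
      right <- if (k == length(h)) 0 else h[k + 1]
      if (h[k] > left && h[k] > right) peaks <- c(peaks, k - 1L)
    }
    if (length(peaks) == 2) return(mean(peaks) / 255)
    if (length(peaks) < 2) return(NA_real_)
    h2 <- h
    for (k in seq_along(h)) {
      left <- if (k == 1) 0 else h[k - 1]
      right <- if (k == length(h)) 0 else h[k + 1]
      h2[k] <- (left + h[k] + right) / 3
    }
    h <- h2
  }
  NA_real_
}

# an edge_map whose 256-bin histogram equals `counts` (needs a matching grid)
em_from_histogram <- function(counts) {
  vals <- rep(0:255, counts) / 255
  n <- length(vals)
  nr <- max(1, floor(sqrt(n)))
  while (n %% nr != 0) nr <- nr - 1
  normalize_edge_map(matrix(vals * 255, nr, n / nr))
}

random_box <- function(width, height) {
  x <- sort(sample(0:(width - 1), 2, replace = TRUE))
  y <- sort(sample(0:(height - 1), 2, replace = TRUE))
  make_box(x[1], y[1], x[2], y[2])
}

small_phantom_config <- function(seed, width = 180, height = 160) {
  set.seed(seed)
  a <- runif(1, 25, 45); b <- runif(1, 20, 38)
  phantom_config(width, height,
                 center = c(runif(1, a + 15, width - 1 - a - 15),
                            runif(1, b + 15, height - 1 - b - 15)),
                 semi_axes = c(a, b), seed = seed)
}
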