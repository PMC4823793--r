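suppressMessages(library(dplyr))

# shared cache so the (expensive) classifier and a rendered demo core are
# built once per test run
.dq_cache <- new.env(parent = emptyenv())

cached_classifier <- function() {
  if (is.null(.dq_cache$clf)) {
    ts <- generate_training_set(crops_per_class = 150, seed = 42)
    .dq_cache$clf <- train_classifier(ts, seed = 42)
  }
  .dq_cache$clf
}

# a small rendered core reused by image-level unit tests (512 px canvas)
cached_small_core <- function() {
  if (is.null(.dq_cache$small)) {
    spec <- core_spec("NON_DELETION", image_size = 512, seed = 11)
    truth <- generate_point_set(spec)
    .dq_cache$small <- list(spec = spec, truth = truth,
                            image = render_core(truth, spec))
  }
  .dq_cache$small
}

# stamp hard (non-antialiased) dark disks onto a white canvas; used where a
# test needs exactly known circle geometry rather than the full renderer
stamp_disks <- function(size, xs, ys, rs, col = c(20L, 20L, 20L)) {
  px <- array(as.raw(255L), dim = c(size, size, 3))
  for (i in seq_along(xs)) {
    x0 <- max(0, floor(xs[i] - rs[i] - 1)); x1 <- min(size - 1, ceiling(xs[i] + rs[i] + 1))
    y0 <- max(0, floor(ys[i] - rs[i] - 1)); y1 <- min(size - 1, ceiling(ys[i] + rs[i] + 1))
    for (x in x0:x1) for (y in y0:y1) {
      if ((x - xs[i])^2 + (y - ys[i])^2 <= rs[i]^2) {
        for (c in 1:3) px[y + 1, x + 1, c] <- as.raw(col[c])
      }
    }
  }
  ish_image(px)
}

# well-spread planted positions on a grid with jitter (deterministic)
spread_positions <- function(n, size, margin = 40, min_dist = 40, seed = 1) {
  withr::with_seed(seed, {
    g <- ceiling(sqrt(n))
    step <- (size - 2 * margin) / g
    stopifnot(step >= min_dist)
    xy <- expand.grid(i = seq_len(g), j = seq_len(g))[seq_len(n), ]
    cbind(x = margin + (xy$i - 0.5) * step + runif(n, -4, 4),
          y = margin + (xy$j - 0.5) * step + runif(n, -4, 4))
  })
}

# labeled planted point set (ground truth labels) for scoring/heterogeneity
truth_points <- function(prototype, seed) {
  truth <- generate_point_set(core_spec(prototype, seed = seed))
  list(points = mutate(truth$points, label = .data$true_label),
       mask = truth$mask, truth = truth)
}
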