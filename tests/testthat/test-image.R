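test_that("images load from PNG/TIFF with grayscale promotion and clean errors", {
  tmp <- withr::local_tempdir()
  img <- cached_small_core()$image

  png_path <- file.path(tmp, "core.png")
  write_image(img, png_path)
  back <- load_image(png_path)
  expect_equal(dim(back$pixels), dim(img$pixels))
  expect_identical(back$pixels, img$pixels)

  gray <- matrix(runif(64 * 64), 64, 64)
  tif_path <- file.path(tmp, "gray.tif")
  EBImage::writeImage(EBImage::Image(gray), tif_path)
  g <- load_image(tif_path)
  expect_equal(dim(g$pixels), c(64, 64, 3))
  expect_identical(g$pixels[, , 1], g$pixels[, , 2])
  expect_identical(g$pixels[, , 1], g$pixels[, , 3])

  bad <- file.path(tmp, "broken.png")
  writeLines("this is not an image", bad)
  expect_error(load_image(bad), class = "dq_format_error")
  expect_error(load_image(file.path(tmp, "absent.png")), class = "dq_format_error")
})

test_that("preprocessing resizes bicubically and is exact on edge cases", {
  # constant field stays constant under bicubic resampling
  const <- ish_image(array(as.raw(c(37L, 120L, 200L))[rep(1:3, each = 64 * 64)],
                           dim = c(64, 64, 3)))
  up <- preprocess_image(const, 256)
  expect_equal(dim(up$pixels), c(256, 256, 3))
  expect_true(all(as.integer(up$pixels[, , 1]) == 37L))
  expect_true(all(as.integer(up$pixels[, , 2]) == 120L))
  expect_true(all(as.integer(up$pixels[, , 3]) == 200L))

  # identity at target size with enhancement off
  img <- cached_small_core()$image
  same <- preprocess_image(img, img_width(img))
  expect_identical(same$pixels, img$pixels)

  # downsizing produces the requested square
  down <- preprocess_image(img, 128)
  expect_equal(dim(down$pixels), c(128, 128, 3))

  expect_error(preprocess_image(img, 32), class = "dq_param_error")
})

test_that("tissue mask coverage tracks planted tissue area", {
  white <- ish_image(array(as.raw(255L), dim = c(128, 128, 3)))
  expect_equal(compute_tissue_mask(white)$coverage_fraction, 0)

  # a rendered core: tissue disk radius 0.47 * size -> area fraction ~0.69
  sm <- cached_small_core()
  m <- compute_tissue_mask(sm$image)
  expect_gt(m$coverage_fraction, 0.6)
  expect_lt(m$coverage_fraction, 0.8)

  # disk covering ~25% of the canvas
  size <- 256
  r <- sqrt(0.25 * size^2 / pi)
  disk <- stamp_disks(size, size / 2, size / 2, r, col = c(150L, 140L, 170L))
  md <- compute_tissue_mask(disk)
  expect_gt(md$coverage_fraction, 0.20)
  expect_lt(md$coverage_fraction, 0.30)

  # fully stained canvas
  full <- ish_image(array(as.raw(c(150L, 140L, 170L))[rep(1:3, each = 128 * 128)],
                          dim = c(128, 128, 3)))
  expect_gte(compute_tissue_mask(full)$coverage_fraction, 0.95)
})

test_that("tiling covers the image and matches stride arithmetic", {
  g <- tile_image(c(4096, 4096), 1024, 0)
  expect_equal(nrow(g), 16)
  expect_true(all(g$x1 - g$x0 == 1024))

  g1 <- tile_image(c(100, 100), 4096, 0)
  expect_equal(nrow(g1), 1)
  expect_equal(c(g1$x1, g1$y1), c(100, 100))

  # brute-force stride enumeration oracle for the overlapped case
  stride_starts <- function(dim, tile, stride) {
    s <- 0; out <- integer(0)
    repeat { out <- c(out, s); if (s + tile >= dim) break; s <- s + stride }
    out
  }
  g2 <- tile_image(c(4096, 4096), 1024, 64)
  expect_equal(nrow(g2), length(stride_starts(4096, 1024, 960))^2)

  # partition-cover: every pixel in >= 1 tile; exactly 1 when overlap = 0
  for (ov in c(0, 16)) {
    gg <- tile_image(c(200, 130), 64, ov)
    cover <- matrix(0L, 130, 200)
    for (i in seq_len(nrow(gg))) {
      cover[(gg$y0[i] + 1):gg$y1[i], (gg$x0[i] + 1):gg$x1[i]] <-
        cover[(gg$y0[i] + 1):gg$y1[i], (gg$x0[i] + 1):gg$x1[i]] + 1L
    }
    expect_true(all(cover >= 1L))
    if (ov == 0) expect_true(all(cover == 1L))
  }

  expect_error(tile_image(c(100, 100), 64, 64), class = "dq_param_error")
})

test_that("tile-detection merging deduplicates and is order-invariant", {
  # same point reported twice -> one survivor
  dup <- tibble::tibble(x = c(10, 10.4), y = c(20, 19.8), strength = c(5, 3))
  expect_equal(nrow(merge_tile_detections(dup, 6)), 1)
  expect_equal(merge_tile_detections(dup, 6)$strength, 5)

  # far-apart points both retained
  far <- tibble::tibble(x = c(0, 200), y = c(0, 0), strength = c(1, 2))
  expect_equal(nrow(merge_tile_detections(far, 6)), 2)

  # random duplicated set vs brute-force greedy suppression
  pts <- withr::with_seed(7, {
    base <- tibble::tibble(x = runif(120, 0, 500), y = runif(120, 0, 500),
                           strength = runif(120, 1, 10))
    jit <- dplyr::mutate(base[sample(120, 60), ],
                         x = x + runif(60, -2, 2), y = y + runif(60, -2, 2),
                         strength = strength * runif(60, 0.5, 0.99))
    dplyr::bind_rows(base, jit)
  })
  greedy <- function(p, sep) {
    p <- p[order(-p$strength, p$x, p$y), ]
    keep <- logical(nrow(p))
    for (i in seq_len(nrow(p))) {
      ok <- TRUE
      for (j in which(keep)) {
        if ((p$x[i] - p$x[j])^2 + (p$y[i] - p$y[j])^2 < sep^2) { ok <- FALSE; break }
      }
      keep[i] <- ok
    }
    p[keep, ]
  }
  got <- merge_tile_detections(pts, 6)
  want <- greedy(pts, 6)
  expect_equal(as.data.frame(got), as.data.frame(want))

  # shuffling the input (tile enumeration order) leaves the result unchanged
  shuf <- withr::with_seed(3, pts[sample(nrow(pts)), ])
  expect_equal(as.data.frame(merge_tile_detections(shuf, 6)),
               as.data.frame(got))
})
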