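# RGB raster images are stored as 8-bit raw arrays with dim c(height, width, 3)
# (row = y increasing downwards, column = x increasing rightwards, 0-based
# coordinates at the API surface). Raw storage keeps whole-slide mosaics
# affordable: a 16,384 x 16,384 slide occupies ~0.8 GB instead of 6.4 GB.

#' Construct a raster image object
#'
#' @param pixels 8-bit raw array with `dim = c(height, width, 3)`, or a numeric
#'   array on `[0, 1]` (converted).
#' @param microns_per_pixel Optional physical resolution (e.g. 0.11 for a 40x
#'   bright-field scan).
#' @return An `ish_image` object.
#' @export
ish_image <- function(pixels, microns_per_pixel = NULL) {
  if (is.double(pixels)) {
    pixels <- array(as.raw(pmin(255L, pmax(0L, as.integer(round(pixels * 255))))),
                    dim = dim(pixels))
  }
  if (!is.raw(pixels) || length(dim(pixels)) != 3 || dim(pixels)[3] != 3) {
    abort("pixels must be a raw or numeric array with dim c(height, width, 3)",
          class = "dq_param_error")
  }
  d <- dim(pixels)
  if (d[1] < 1 || d[2] < 1) abort("image must be at least 1x1", class = "dq_param_error")
  structure(list(pixels = pixels, microns_per_pixel = microns_per_pixel),
            class = "ish_image")
}

#' @export
dim.ish_image <- function(x) dim(x$pixels)

#' Image height/width in pixels
#' @param image An `ish_image`.
#' @return Integer scalar.
#' @export
img_height <- function(image) dim(image$pixels)[1]

#' @rdname img_height
#' @export
img_width <- function(image) dim(image$pixels)[2]

#' @export
print.ish_image <- function(x, ...) {
  cat(sprintf("<ish_image> %d x %d px (w x h)%s\n", img_width(x), img_height(x),
              if (!is.null(x$microns_per_pixel))
                sprintf(", %.3g um/px", x$microns_per_pixel) else ""))
  invisible(x)
}

#' Convert an image to a numeric array on [0, 1]
#' @param image An `ish_image`.
#' @return Numeric array `c(height, width, 3)`.
#' @export
as_numeric_array <- function(image) {
  a <- array(as.integer(image$pixels), dim = dim(image$pixels))
  a / 255
}

#' Load a bright-field RGB image
#'
#' Reads TIFF, PNG or JPEG files into an 8-bit RGB raster. Grayscale inputs
#' are promoted to RGB by channel replication.
#'
#' @param path Path to the image file.
#' @param microns_per_pixel Optional physical resolution to record.
#' @return An [ish_image].
#' @export
load_image <- function(path, microns_per_pixel = NULL) {
  if (!file.exists(path)) {
    abort(paste0("image file not found: ", path), class = "dq_format_error")
  }
  img <- tryCatch(suppressWarnings(EBImage::readImage(path)),
                  error = function(e) {
                    abort(paste0("cannot read image '", path, "': ",
                                 conditionMessage(e)), class = "dq_format_error")
                  })
  a <- EBImage::imageData(img)   # EBImage layout: (x, y[, channel])
  if (length(dim(a)) == 2) {
    a <- array(rep(a, 3), dim = c(dim(a), 3))
  } else if (dim(a)[3] > 3) {
    a <- a[, , 1:3, drop = FALSE]  # drop alpha
  } else if (dim(a)[3] < 3) {
    a <- array(rep(a[, , 1], 3), dim = c(dim(a)[1:2], 3))
  }
  a <- aperm(a, c(2, 1, 3))        # to (y, x, channel)
  a[a < 0] <- 0; a[a > 1] <- 1
  ish_image(a, microns_per_pixel = microns_per_pixel)
}

#' Write an image to disk (PNG/TIFF/JPEG by extension)
#' @param image An [ish_image].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  a <- aperm(as_numeric_array(image), c(2, 1, 3))
  EBImage::writeImage(EBImage::Image(a, colormode = "Color"), path)
  invisible(path)
}

#' Preprocess an image to the working resolution
#'
#' Resizes to a square working frame by bicubic interpolation (Catmull-Rom
#' kernel). The 4096 x 4096 default gives efficient power-of-two tiling.
#' Optional gray-world white balance and percentile contrast stretch are
#' provided for scans without auto-correction; both are disabled by default
#' since scanners normally apply their own white balance and contrast
#' correction before export.
#'
#' @param image An [ish_image].
#' @param target_size Output side length in pixels (default 4096).
#' @param white_balance Apply gray-world white balance (default `FALSE`).
#' @param contrast_stretch Apply a 1st-99th percentile linear stretch
#'   (default `FALSE`).
#' @return An [ish_image] of size `target_size` x `target_size`.
#' @export
preprocess_image <- function(image, target_size = 4096,
                             white_balance = FALSE, contrast_stretch = FALSE) {
  if (target_size < 64) abort("target_size must be >= 64", class = "dq_param_error")
  d <- dim(image$pixels)
  px <- image$pixels
  if (d[1] != target_size || d[2] != target_size) {
    px <- cpp_resize_bicubic(px, d[1], d[2], as.integer(target_size),
                             as.integer(target_size))
    dim(px) <- c(target_size, target_size, 3)
  }
  if (white_balance || contrast_stretch) {
    a <- array(as.integer(px), dim = dim(px))
    if (white_balance) {
      chm <- apply(a, 3, mean)
      for (c in 1:3) a[, , c] <- a[, , c] * (mean(chm) / max(chm[c], 1e-6))
    }
    if (contrast_stretch) {
      q <- quantile(a, c(0.01, 0.99))
      a <- (a - q[1]) / max(q[2] - q[1], 1e-6) * 255
    }
    a <- pmin(255, pmax(0, round(a)))
    px <- array(as.raw(a), dim = dim(px))
  }
  ish_image(px, microns_per_pixel = {
    if (!is.null(image$microns_per_pixel))
      image$microns_per_pixel * d[2] / target_size else NULL
  })
}

# ---------------------------------------------------------------------------
# tissue masks
# ---------------------------------------------------------------------------

#' Create a tissue mask object from a logical matrix
#' @param mask Logical matrix (height x width), `TRUE` on tissue.
#' @return An `ish_mask` with a `coverage_fraction` field.
#' @export
ish_mask <- function(mask) {
  structure(list(mask = mask, coverage_fraction = mean(mask)),
            class = "ish_mask")
}

#' Lightweight circular tissue mask
#'
#' Describes a disk-shaped tissue region without materializing a pixel mask;
#' used by the synthetic generator and accepted everywhere an `ish_mask` is.
#'
#' @param cx,cy Disk centre (pixels, 0-based).
#' @param radius Disk radius in pixels.
#' @param width,height Canvas dimensions.
#' @return An `ish_disk_mask`.
#' @export
disk_mask <- function(cx, cy, radius, width, height) {
  structure(list(cx = cx, cy = cy, radius = radius,
                 width = width, height = height,
                 coverage_fraction = min(1, pi * radius^2 / (width * height))),
            class = "ish_disk_mask")
}

#' Segment tissue from background
#'
#' Thresholds saturation and luminance (tissue is darker and more saturated
#' than the near-white background) and removes small objects by a morphological
#' opening.
#'
#' @param image An [ish_image].
#' @param luminance_max Pixels darker than this (0-1 scale) count as tissue.
#' @param saturation_min Pixels more saturated than this count as tissue.
#' @param clean_radius Disc radius of the morphological opening (0 disables).
#' @return An [ish_mask].
#' @export
compute_tissue_mask <- function(image, luminance_max = 0.92,
                                saturation_min = 0.10, clean_radius = 2) {
  d <- dim(image$pixels)
  r <- array(as.integer(image$pixels[, , 1]), dim = d[1:2])
  g <- array(as.integer(image$pixels[, , 2]), dim = d[1:2])
  b <- array(as.integer(image$pixels[, , 3]), dim = d[1:2])
  lum <- (0.299 * r + 0.587 * g + 0.114 * b) / 255
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  sat <- ifelse(mx > 0, (mx - mn) / mx, 0)
  m <- lum < luminance_max | sat > saturation_min
  if (clean_radius > 0 && any(m)) {
    k <- EBImage::makeBrush(2 * clean_radius + 1, shape = "disc")
    m <- EBImage::imageData(EBImage::opening(EBImage::Image(m * 1), k)) > 0.5
  }
  ish_mask(m)
}

# TRUE/FALSE membership of (x, y) points in a mask; mask = NULL accepts all
mask_contains <- function(mask, x, y) {
  if (is.null(mask)) return(rep(TRUE, length(x)))
  if (inherits(mask, "ish_disk_mask")) {
    return((x - mask$cx)^2 + (y - mask$cy)^2 <= mask$radius^2)
  }
  m <- mask$mask
  i <- pmin(nrow(m), pmax(1, round(y) + 1))
  j <- pmin(ncol(m), pmax(1, round(x) + 1))
  m[cbind(i, j)]
}

mask_dims <- function(mask) {
  if (inherits(mask, "ish_disk_mask")) c(mask$height, mask$width)
  else dim(mask$mask)
}

# uniform random points inside a mask (rejection for pixel masks,
# polar sampling for disk masks); caller controls the RNG seed
uniform_in_mask <- function(mask, n) {
  if (inherits(mask, "ish_disk_mask")) {
    r <- mask$radius * sqrt(runif(n))
    th <- runif(n, 0, 2 * pi)
    return(cbind(x = mask$cx + r * cos(th), y = mask$cy + r * sin(th)))
  }
  m <- mask$mask
  if (!any(m)) abort("mask is empty", class = "dq_data_error")
  h <- nrow(m); w <- ncol(m)
  out <- matrix(numeric(0), ncol = 2)
  while (nrow(out) < n) {
    k <- max(64, ceiling((n - nrow(out)) / max(mean(m), 1e-3)))
    x <- runif(k, 0, w); y <- runif(k, 0, h)
    keep <- m[cbind(floor(y) + 1, floor(x) + 1)]
    out <- rbind(out, cbind(x, y)[keep, , drop = FALSE])
  }
  colnames(out) <- c("x", "y")
  out[seq_len(n), , drop = FALSE]
}

# ---------------------------------------------------------------------------
# tiling
# ---------------------------------------------------------------------------

#' Tile an image into half-open pixel rectangles
#'
#' Tiles start at multiples of `tile_size - overlap`; border tiles are clipped
#' to the image edge and may be smaller. Every pixel is covered by at least one
#' tile (exactly one when `overlap = 0`).
#'
#' @param image An [ish_image], or a `c(width, height)` integer vector.
#' @param tile_size Tile side length in pixels.
#' @param overlap Overlap between adjacent tiles in pixels (default 64).
#' @return An `ish_tile_grid`: a tibble with columns `tile_id`, `x0`, `y0`,
#'   `x1`, `y1` (half-open) and attributes `tile_size`, `overlap`.
#' @export
tile_image <- function(image, tile_size = 4096, overlap = 64) {
  if (overlap < 0 || tile_size <= overlap) {
    abort("need tile_size > overlap >= 0", class = "dq_param_error")
  }
  if (inherits(image, "ish_image")) {
    w <- img_width(image); h <- img_height(image)
  } else {
    w <- image[1]; h <- image[2]
  }
  stride <- tile_size - overlap
  starts <- function(dim) {
    s <- 0L; out <- integer(0)
    repeat {
      out <- c(out, s)
      if (s + tile_size >= dim) break
      s <- s + stride
    }
    out
  }
  sx <- starts(w); sy <- starts(h)
  g <- expand.grid(x0 = sx, y0 = sy)
  out <- tibble(
    tile_id = seq_len(nrow(g)),
    x0 = g$x0, y0 = g$y0,
    x1 = pmin(g$x0 + tile_size, w),
    y1 = pmin(g$y0 + tile_size, h)
  )
  structure(out, tile_size = tile_size, overlap = overlap,
            canvas = c(w, h), class = c("ish_tile_grid", class(out)))
}

#' Extract one tile from an image
#' @param image An [ish_image].
#' @param tile One row of an `ish_tile_grid` (or a list with x0, y0, x1, y1).
#' @return An [ish_image] holding the tile.
#' @export
crop_tile <- function(image, tile) {
  px <- image$pixels[(tile$y0 + 1):tile$y1, (tile$x0 + 1):tile$x1, , drop = FALSE]
  ish_image(px, microns_per_pixel = image$microns_per_pixel)
}

#' Merge per-tile detections from overlap zones
#'
#' Deduplicates signals reported by more than one tile: no two retained points
#' lie closer than `min_separation`; among duplicates, the point with the
#' larger detection strength wins (ties broken by x, then y, so the result is
#' independent of tile enumeration order).
#'
#' @param points Tibble of signals in global coordinates with columns
#'   `x`, `y`, `strength` (extra columns are carried along).
#' @param min_separation Minimum pairwise distance in pixels.
#' @return The deduplicated tibble, sorted by decreasing strength.
#' @export
merge_tile_detections <- function(points, min_separation = 6) {
  if (nrow(points) == 0) return(points)
  keep <- cpp_nms(points$x, points$y, points$strength, min_separation)
  points[keep, , drop = FALSE] |>
    arrange(desc(.data$strength), .data$x, .data$y)
}
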