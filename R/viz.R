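#' Colour-map rendering style
#'
#' Classified signals are drawn as coloured glyphs preserving tissue
#' topology: black for gene, red for CEP, green for colocalized gene+CEP.
#'
#' @param gene_colour,cep_colour,mixed_colour Glyph colours (must be distinct).
#' @param glyph Glyph shape (only `"square"` is rasterized).
#' @param glyph_size Glyph side length in pixels (odd recommended).
#' @param background `"white"` or `"dimmed_tissue"`.
#' @return A `dq_colour_map_style`.
#' @export
colour_map_style <- function(gene_colour = "black", cep_colour = "red",
                             mixed_colour = "green3", glyph = "square",
                             glyph_size = 9,
                             background = c("white", "dimmed_tissue")) {
  background <- match.arg(background)
  cols <- c(gene_colour, cep_colour, mixed_colour)
  if (length(unique(cols)) != 3) {
    abort("the three glyph colours must be distinct", class = "dq_param_error")
  }
  structure(list(gene_colour = gene_colour, cep_colour = cep_colour,
                 mixed_colour = mixed_colour, glyph = glyph,
                 glyph_size = as.integer(glyph_size), background = background),
            class = "dq_colour_map_style")
}

#' Render a signal colour map
#'
#' Rasterizes one glyph per GENE/CEP/GENE_CEP_MIXED signal at its detected
#' coordinates (noise and cell stains are omitted); positions are not
#' rescaled, so the map preserves tissue geometry.
#'
#' @param points Labeled signal tibble.
#' @param canvas `c(width, height)` in pixels.
#' @param style A [colour_map_style].
#' @param tissue Optional [ish_image] used for the `dimmed_tissue` background.
#' @return An [ish_image].
#' @export
render_colour_map <- function(points, canvas, style = colour_map_style(),
                              tissue = NULL) {
  w <- canvas[1]; h <- canvas[2]
  if (style$background == "dimmed_tissue" && !is.null(tissue)) {
    a <- as.integer(tissue$pixels)
    px <- array(as.raw(pmin(255L, 180L + a %/% 3L)), dim = c(h, w, 3))
  } else {
    px <- array(as.raw(255L), dim = c(h, w, 3))
  }
  cols <- grDevices::col2rgb(c(GENE = style$gene_colour, CEP = style$cep_colour,
                               GENE_CEP_MIXED = style$mixed_colour))
  half <- style$glyph_size %/% 2L
  keep <- points$label %in% c("GENE", "CEP", "GENE_CEP_MIXED")
  pts <- points[keep, , drop = FALSE]
  for (i in seq_len(nrow(pts))) {
    x <- round(pts$x[i]); y <- round(pts$y[i])
    x0 <- max(0, x - half); x1 <- min(w - 1, x + half)
    y0 <- max(0, y - half); y1 <- min(h - 1, y + half)
    if (x0 > x1 || y0 > y1) next
    cc <- cols[, match(pts$label[i], colnames(cols))]
    for (c in 1:3) px[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), c] <- as.raw(cc[c])
  }
  ish_image(px)
}

#' Local-ratio bar grid over fixed square tiles
#'
#' Divides the canvas into `tile_size` squares and scores the gene/CEP ratio
#' of each tile with [global_ratio()]; tiles whose effective CEP count falls
#' below `min_cep` are left undefined (`NA`). The grid is the quantitative
#' backing of the 3-D "bar graph" view of whole-slide heterogeneity, rendered
#' here as a heat map for testability.
#'
#' @param points Labeled signal tibble (global coordinates).
#' @param canvas `c(width, height)` in pixels.
#' @param tile_size Tile side length in pixels (>= 32).
#' @param min_cep Minimum effective CEP count for a defined tile (default 3).
#' @param mixed_policy See [global_ratio()].
#' @return An `ish_bargrid`: `ratio` matrix (rows = tile rows = y), matching
#'   `gene_count`/`cep_count` matrices, `tile_size`, `min_cep`.
#' @export
compute_bar_grid <- function(points, canvas, tile_size = 512, min_cep = 3,
                             mixed_policy = c("count_both", "exclude")) {
  mixed_policy <- match.arg(mixed_policy)
  if (tile_size < 32) abort("tile_size must be >= 32", class = "dq_param_error")
  w <- canvas[1]; h <- canvas[2]
  nx <- ceiling(w / tile_size); ny <- ceiling(h / tile_size)
  tx <- pmin(nx - 1, pmax(0, floor(points$x / tile_size)))
  ty <- pmin(ny - 1, pmax(0, floor(points$y / tile_size)))
  g <- matrix(0L, ny, nx); c_ <- matrix(0L, ny, nx); m <- matrix(0L, ny, nx)
  for (i in seq_len(nrow(points))) {
    lb <- points$label[i]
    if (lb == "GENE") g[ty[i] + 1, tx[i] + 1] <- g[ty[i] + 1, tx[i] + 1] + 1L
    else if (lb == "CEP") c_[ty[i] + 1, tx[i] + 1] <- c_[ty[i] + 1, tx[i] + 1] + 1L
    else if (lb == "GENE_CEP_MIXED") m[ty[i] + 1, tx[i] + 1] <- m[ty[i] + 1, tx[i] + 1] + 1L
  }
  if (mixed_policy == "count_both") {
    num <- g + m; den <- c_ + m
  } else {
    num <- g; den <- c_
  }
  ratio <- ifelse(den >= min_cep, num / pmax(den, 1L), NA_real_)
  structure(list(ratio = ratio, gene_count = g, cep_count = c_, mixed_count = m,
                 tile_size = tile_size, min_cep = min_cep,
                 mixed_policy = mixed_policy, canvas = canvas),
            class = "ish_bargrid")
}

#' @method tidy ish_bargrid
#' @export
tidy.ish_bargrid <- function(x, ...) {
  ny <- nrow(x$ratio); nx <- ncol(x$ratio)
  tibble(tile_x = rep(seq_len(nx) - 1L, each = ny),
         tile_y = rep(seq_len(ny) - 1L, nx),
         gene_count = as.vector(x$gene_count),
         cep_count = as.vector(x$cep_count),
         mixed_count = as.vector(x$mixed_count),
         ratio = as.vector(x$ratio))
}

#' @method autoplot ish_bargrid
#' @export
autoplot.ish_bargrid <- function(object, ...) {
  df <- tidy(object)
  ggplot(df[!is.na(df$ratio), ], aes(x = .data$tile_x, y = .data$tile_y,
                                     fill = .data$ratio)) +
    geom_tile() +
    scale_fill_viridis_c(limits = c(0, NA)) +
    scale_y_reverse() +
    coord_fixed() +
    labs(x = "tile column", y = "tile row", fill = "gene/CEP") +
    theme_minimal()
}

ellipse_path <- function(cx, cy, a, b, theta, n = 90) {
  t <- seq(0, 2 * pi, length.out = n)
  tibble(x = cx + a * cos(t) * cos(theta) - b * sin(t) * sin(theta),
         y = cy + a * cos(t) * sin(theta) + b * sin(t) * cos(theta))
}

#' @method autoplot ish_embedding
#' @export
autoplot.ish_embedding <- function(object, model = NULL, ellipses = NULL,
                                   distances = NULL, ...) {
  df <- object$coords
  df$cluster <- if (!is.null(model)) factor(model$assignments) else factor(1)
  p <- ggplot(df, aes(x = .data$PC1, y = .data$PC2)) +
    geom_point(aes(colour = .data$cluster), size = 2) +
    labs(x = sprintf("PC1 (%.0f%%)", 100 * object$explained_variance[1]),
         y = sprintf("PC2 (%.0f%%)", 100 * object$explained_variance[2])) +
    theme_minimal()
  if (!is.null(ellipses)) {
    paths <- bind_rows(lapply(seq_len(nrow(ellipses)), function(i) {
      e <- ellipses[i, ]
      mutate(ellipse_path(e$center_1, e$center_2, e$axis_major, e$axis_minor,
                          e$orientation), core_id = e$core_id)
    }))
    p <- p + geom_path(data = paths, aes(x = .data$x, y = .data$y,
                                         group = .data$core_id),
                       linewidth = 0.2, colour = "grey50")
  }
  if (!is.null(model)) {
    ctr <- tibble(PC1 = model$means[, 1], PC2 = model$means[, 2])
    p <- p + geom_point(data = ctr, shape = 8, size = 4, colour = "black")
  }
  if (!is.null(distances)) {
    p <- p + geom_text(aes(label = sprintf("%.1f", distances)),
                       vjust = -1, size = 2.5)
  }
  p
}

#' Render the PCA embedding figure with clusters, ellipses and distances
#'
#' Writes the core-distribution scatter (coloured by mixture cluster, with
#' perturbation ellipses, per-core Mahalanobis annotations, and starred
#' centroids) plus a machine-readable CSV sidecar carrying everything the
#' figure shows.
#'
#' @param embedding An `ish_embedding`.
#' @param model Optional `ish_gmm`.
#' @param ellipses Optional tibble from [perturbation_ellipses()].
#' @param distances Optional numeric vector (per core).
#' @param file Output figure path (`.pdf` or `.png` by extension).
#' @param sidecar Sidecar CSV path (default `file` + `.csv`).
#' @return `file`, invisibly.
#' @export
render_embedding <- function(embedding, model = NULL, ellipses = NULL,
                             distances = NULL, file,
                             sidecar = paste0(file, ".csv")) {
  p <- autoplot(embedding, model = model, ellipses = ellipses,
                distances = distances)
  dev <- if (grepl("\\.png$", file) && capabilities("png")) "png" else NULL
  suppressMessages(ggsave(file, p, width = 6, height = 5, dpi = 150, device = dev))
  side <- embedding$coords
  if (!is.null(model)) side$cluster <- model$assignments
  if (!is.null(distances)) side$mahalanobis_to_reference <- distances
  if (!is.null(ellipses)) side <- left_join(side, ellipses, by = "core_id")
  readr::write_csv(side, sidecar)
  invisible(file)
}
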