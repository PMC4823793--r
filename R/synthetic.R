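# Synthetic DISH cores with full ground truth. The generator emulates the six
# heterogeneity prototypes seen in real tissue: homogeneous events (homozygous
# deletion, hemizygous deletion, non-deletion), cellular heterogeneity with
# homogeneous or heterogeneous genotype, and spatially organized intra-tumour
# heterogeneity (ITH).

#' The six heterogeneity prototypes
#' @return Character vector of prototype names.
#' @export
core_prototypes <- function() {
  c("HOMOZYGOUS_DELETION", "HEMIZYGOUS_DELETION", "NON_DELETION",
    "CELLULAR_HET_HOMOGENEOUS_GENOTYPE", "CELLULAR_HET_HETEROGENEOUS_GENOTYPE",
    "INTRATUMOUR_HET")
}

#' Specify a synthetic DISH core
#'
#' Builds the generative specification for one tissue core: cell geometry and
#' genotype per spatial region, probe copy numbers, sectioning signal loss,
#' colocalization, and background noise/stain densities. Prototype presets:
#' \describe{
#'   \item{NON_DELETION}{two gene copies everywhere (expected ratio 1.0).}
#'   \item{HEMIZYGOUS_DELETION}{one gene copy everywhere (ratio 0.5).}
#'   \item{HOMOZYGOUS_DELETION}{zero gene copies in the core centre with a
#'     narrow benign rim retaining two copies, mimicking retained basal
#'     cells (ratio ~ 0.28).}
#'   \item{CELLULAR_HET_HOMOGENEOUS_GENOTYPE}{uniform genotype (two copies)
#'     but strongly uneven cellularity across tumour nests, as in
#'     lymphoid-rich tissue.}
#'   \item{CELLULAR_HET_HETEROGENEOUS_GENOTYPE}{tumour (zero copies) and
#'     benign (two copies) cells intermixed 50:50 across unevenly occupied
#'     nests (ratio 0.5), as in a partly involved lymph node.}
#'   \item{INTRATUMOUR_HET}{half-plane split: two copies on the left, zero on
#'     the right (ratio 0.5, strongly spatially organized).}
#' }
#' Default densities put a core in the 1,000-5,000 signals band, with roughly
#' 30% of signals being gene/CEP and the rest background noise and stains.
#'
#' @param prototype One of [core_prototypes()].
#' @param image_size Canvas side length in pixels (default 4096).
#' @param n_cells Number of cells; default scales the 4096-px value (420) by
#'   canvas area.
#' @param cep_copies CEP copies per cell (default 2).
#' @param signal_loss_prob Per-signal sectioning loss probability, applied
#'   equally to both channels so the expected ratio is preserved (default 0.15).
#' @param colocalization_prob Probability that a gene/CEP pair in the same
#'   cell renders as a single colocalized `GENE_CEP_MIXED` signal (default 0.05).
#' @param noise_density,stain_density Background events per squared pixel of
#'   tissue (defaults 2.6e-4 and 4e-6).
#' @param dot_radius_range Signal dot radius range in pixels (default 3-6).
#' @param cell_radius,cell_spacing Cell geometry: dots scatter within
#'   `cell_radius` of the cell centre; cell centres keep `cell_spacing` apart
#'   (hard-core process within nests).
#' @param n_parents,cluster_sd Tumour-nest geometry: cells scatter around
#'   `n_parents` nest centres (Thomas-like process) with SD `cluster_sd`
#'   pixels, emulating tumour foci/glands; dense nests make the 60-px local
#'   neighbourhoods contain several adjacent cells, as in real tissue.
#' @param seed Integer seed; everything downstream is deterministic in it.
#' @param regions Optional custom region list overriding the preset: each
#'   element is `list(copies =, probs =)` giving the per-cell gene copy
#'   mixture of that region.
#' @param region_geometry `"whole"`, `"half_plane"` or `"blob"`.
#' @param split_frac For `half_plane`: position of the region boundary as a
#'   fraction of the canvas width (0.5 = through the core centre).
#' @param clustered With uneven nest weights (the cellular-heterogeneity
#'   preset): nest occupancies drawn unevenly, producing strong
#'   cell-density variation at homogeneous genotype.
#' @return An `ish_core_spec`.
#' @export
core_spec <- function(prototype = "NON_DELETION", image_size = 4096,
                      n_cells = NULL, cep_copies = 2,
                      signal_loss_prob = 0.15, colocalization_prob = 0.05,
                      noise_density = 2.6e-4, stain_density = 4e-6,
                      dot_radius_range = c(3, 6),
                      cell_radius = 16, cell_spacing = 40,
                      n_parents = NULL, cluster_sd = 70,
                      seed = 1, regions = NULL, region_geometry = NULL,
                      split_frac = 0.5, clustered = NULL) {
  prototype <- match.arg(prototype, core_prototypes())
  if (signal_loss_prob < 0 || signal_loss_prob > 1 ||
      colocalization_prob < 0 || colocalization_prob > 1) {
    abort("probabilities must be in [0, 1]", class = "dq_param_error")
  }
  preset <- switch(prototype,
    NON_DELETION = list(geometry = "whole",
                        regions = list(list(copies = 2, probs = 1)),
                        clustered = FALSE),
    HEMIZYGOUS_DELETION = list(geometry = "whole",
                               regions = list(list(copies = 1, probs = 1)),
                               clustered = FALSE),
    HOMOZYGOUS_DELETION = list(geometry = "blob",
                               regions = list(list(copies = 0, probs = 1),
                                              list(copies = 2, probs = 1)),
                               clustered = FALSE),
    CELLULAR_HET_HOMOGENEOUS_GENOTYPE = list(geometry = "whole",
                                             regions = list(list(copies = 2, probs = 1)),
                                             clustered = TRUE, cellularity = 1.35),
    CELLULAR_HET_HETEROGENEOUS_GENOTYPE = list(geometry = "whole",
                                               regions = list(list(copies = c(0, 2),
                                                                   probs = c(0.5, 0.5))),
                                               clustered = TRUE, cellularity = 1.55),
    INTRATUMOUR_HET = list(geometry = "half_plane",
                           regions = list(list(copies = 2, probs = 1),
                                          list(copies = 0, probs = 1)),
                           clustered = FALSE)
  )
  geometry <- region_geometry %||% preset$geometry
  regions <- regions %||% preset$regions
  clustered <- clustered %||% preset$clustered
  n_need <- switch(geometry, whole = 1L, half_plane = 2L, blob = 2L)
  if (length(regions) != n_need) {
    abort(sprintf("geometry '%s' needs %d region(s), got %d",
                  geometry, n_need, length(regions)), class = "dq_param_error")
  }
  cellularity <- preset$cellularity %||% 1
  if (is.null(n_cells)) {
    n_cells <- max(10L, round(420 * cellularity * (image_size / 4096)^2))
  }
  if (is.null(n_parents)) n_parents <- max(3L, round(n_cells / 35))
  structure(list(
    prototype = prototype, image_size = as.integer(image_size),
    n_cells = as.integer(n_cells), cep_copies = as.integer(cep_copies),
    signal_loss_prob = signal_loss_prob,
    colocalization_prob = colocalization_prob,
    noise_density = noise_density, stain_density = stain_density,
    dot_radius_range = dot_radius_range,
    cell_radius = cell_radius, cell_spacing = cell_spacing,
    n_parents = as.integer(n_parents), cluster_sd = cluster_sd,
    region_geometry = geometry, regions = regions, clustered = clustered,
    blob_inner_frac = 0.85, split_frac = split_frac, seed = as.integer(seed)
  ), class = "ish_core_spec")
}

region_of <- function(spec, x, y, mask) {
  switch(spec$region_geometry,
         whole = rep(1L, length(x)),
         half_plane = ifelse(
           x < mask$cx + (spec$split_frac - 0.5) * 2 * mask$radius, 1L, 2L),
         blob = ifelse((x - mask$cx)^2 + (y - mask$cy)^2 <=
                         (spec$blob_inner_frac * mask$radius)^2, 1L, 2L))
}

#' Generate a planted signal point set with ground truth
#'
#' Cells are placed inside a disk-shaped tissue mask by a hard-core
#' (minimum-distance) random process (or a clustered variant for the
#' cellular-heterogeneity prototype). Each cell draws its gene copy number
#' from its region's genotype mixture, then emits Binomial(copies, 1 - loss)
#' gene dots and Binomial(cep_copies, 1 - loss) CEP dots jittered within the
#' cell radius; gene/CEP pairs colocalize into `GENE_CEP_MIXED` signals with
#' the configured probability. Background noise dots and large diffuse cell
#' stains are added at their per-area densities. All dot-like signals keep a
#' minimum pairwise distance so planted signals remain individually
#' resolvable.
#'
#' @param spec An [core_spec()].
#' @return An `ish_truth`: `points` (tibble `x`, `y`, `radius`, `true_label`,
#'   `region_id`, `cell_id`), `mask` (a [disk_mask]), `regions` (per-region
#'   planted and realized ratios), `expected_global_ratio`, and `spec`.
#' @export
generate_point_set <- function(spec) {
  size <- spec$image_size
  mask <- disk_mask(size / 2, size / 2, 0.47 * size, size, size)
  withr::with_seed(spec$seed, {
    # --- cell centres: hard-core process inside Thomas-like tumour nests.
    # The cellular-heterogeneity presets use a two-population layout: half
    # the cells in tight nests, half diffuse over the core, so local density
    # varies strongly while the genotype model is untouched. ---
    n_par <- spec$n_parents
    pr <- mask$radius * sqrt(runif(n_par))
    pth <- runif(n_par, 0, 2 * pi)
    parents <- cbind(mask$cx + pr * cos(pth), mask$cy + pr * sin(pth))
    if (spec$clustered) {
      n1 <- floor(spec$n_cells * 0.8)
      c1 <- cpp_hardcore_disk(n1, mask$cx, mask$cy, mask$radius,
                              spec$cell_spacing, 60L * n1 + 2000L,
                              parents, runif(n_par) + 0.05,
                              spec$cluster_sd * 0.8)
      c2 <- cpp_hardcore_disk(spec$n_cells - n1, mask$cx, mask$cy, mask$radius,
                              spec$cell_spacing, 60L * spec$n_cells + 2000L,
                              matrix(numeric(0), 0, 2), numeric(0), 0)
      centres <- rbind(c1, c2)
    } else {
      centres <- cpp_hardcore_disk(spec$n_cells, mask$cx, mask$cy, mask$radius,
                                   spec$cell_spacing,
                                   60L * spec$n_cells + 2000L, parents,
                                   rep(1, n_par), spec$cluster_sd)
    }
    if (nrow(centres) < spec$n_cells) {
      abort(sprintf("infeasible packing: placed %d of %d cells",
                    nrow(centres), spec$n_cells), class = "dq_data_error")
    }
    region <- region_of(spec, centres[, 1], centres[, 2], mask)
    # expected ratio conditional on the realized cell-to-region assignment
    # (independent of the loss probability, which hits both channels equally)
    e_copies <- vapply(spec$regions, function(r) sum(r$copies * r$probs),
                       numeric(1))
    exp_ratio <- sum(e_copies[region]) / (length(region) * spec$cep_copies)

    # --- per-cell copy numbers and dot labels ---
    cp <- vapply(region, function(r) {
      reg <- spec$regions[[r]]
      if (length(reg$copies) == 1) reg$copies else
        sample(reg$copies, 1, prob = reg$probs)
    }, numeric(1))
    ng <- rbinom(spec$n_cells, cp, 1 - spec$signal_loss_prob)
    nc <- rbinom(spec$n_cells, spec$cep_copies, 1 - spec$signal_loss_prob)
    nmix <- rbinom(spec$n_cells, pmin(ng, nc), spec$colocalization_prob)
    per_cell <- lapply(seq_len(spec$n_cells), function(i) {
      labs <- c(rep("GENE", ng[i] - nmix[i]), rep("CEP", nc[i] - nmix[i]),
                rep("GENE_CEP_MIXED", nmix[i]))
      if (length(labs) > 1) labs <- sample(labs)  # channel-symmetric order
      labs
    })
    n_dots <- lengths(per_cell)
    cell_id <- rep(seq_len(spec$n_cells), n_dots)
    labels <- unlist(per_cell)

    # --- background noise centres ---
    area <- pi * mask$radius^2
    n_noise <- rpois(1, spec$noise_density * area)
    noise_ctr <- uniform_in_mask(mask, n_noise)

    # --- global hard-core placement of every dot-like signal ---
    dot_sep <- 2 * spec$dot_radius_range[1] + 4
    placed <- cpp_place_dots(
      c(centres[cell_id, 1], noise_ctr[, 1]),
      c(centres[cell_id, 2], noise_ctr[, 2]),
      c(rep(spec$cell_radius, length(cell_id)), rep(6, n_noise)),
      dot_sep, size, size)
    radii <- c(runif(length(cell_id), spec$dot_radius_range[1],
                     spec$dot_radius_range[2]),
               runif(n_noise, 3, 5))
    all_labels <- c(labels, rep("NOISE", n_noise))
    all_region <- c(region[cell_id], rep(NA_integer_, n_noise))
    all_cell <- c(cell_id, rep(NA_integer_, n_noise))
    ok <- placed[, 3] > 0
    points <- tibble(x = placed[ok, 1], y = placed[ok, 2], radius = radii[ok],
                     true_label = all_labels[ok], region_id = all_region[ok],
                     cell_id = all_cell[ok])

    # --- large diffuse stains (no separation constraint) ---
    n_stain <- rpois(1, spec$stain_density * area)
    if (n_stain > 0) {
      ctr <- uniform_in_mask(mask, n_stain)
      points <- bind_rows(points, tibble(
        x = ctr[, 1], y = ctr[, 2], radius = runif(n_stain, 18, 40),
        true_label = "CELL_STAIN", region_id = NA_integer_,
        cell_id = NA_integer_))
    }

    # per-region realized ratios (mixed counts in both channels)
    regs <- lapply(seq_along(spec$regions), function(r) {
      p <- points[!is.na(points$region_id) & points$region_id == r, ]
      g <- sum(p$true_label == "GENE") + sum(p$true_label == "GENE_CEP_MIXED")
      c_ <- sum(p$true_label == "CEP") + sum(p$true_label == "GENE_CEP_MIXED")
      tibble(region_id = r,
             expected_ratio = sum(spec$regions[[r]]$copies * spec$regions[[r]]$probs) /
               spec$cep_copies,
             gene_count = g, cep_count = c_,
             realized_ratio = if (c_ > 0) g / c_ else NA_real_)
    })
    structure(list(points = points, mask = mask, regions = bind_rows(regs),
                   expected_global_ratio = exp_ratio, spec = spec),
              class = "ish_truth")
  })
}

#' @export
print.ish_truth <- function(x, ...) {
  cat(sprintf("<ish_truth> %s: %d planted signals, expected ratio %.3f\n",
              x$spec$prototype, nrow(x$points), x$expected_global_ratio))
  invisible(x)
}

label_code <- function(label) {
  match(label, signal_classes())
}

#' Render a synthetic core to a bright-field image
#'
#' Draws a pale, textured hematoxylin-like background inside the tissue disk
#' (white outside), then the planted signals: near-black gene dots, red CEP
#' dots, colocalized mixed signals as overlapping black + red pairs, faint
#' grey noise speckle, and large diffuse bluish cell stains; finally adds
#' sensor noise. Deterministic in the spec seed.
#'
#' @param truth An `ish_truth` from [generate_point_set()].
#' @param spec The core spec (defaults to `truth$spec`).
#' @return An [ish_image] of size `spec$image_size` squared.
#' @export
render_core <- function(truth, spec = truth$spec) {
  size <- spec$image_size
  pts <- truth$points
  m <- withr::with_seed(spec$seed + 500009L, {
    cbind(pts$x, pts$y, pts$radius, label_code(pts$true_label),
          runif(nrow(pts), 0, 2 * pi))
  })
  px <- withr::with_seed(spec$seed + 911L, {
    cpp_render_core(size, size, m, truth$mask$cx, truth$mask$cy,
                    truth$mask$radius, 2.5)
  })
  dim(px) <- c(size, size, 3)
  ish_image(px)
}

#' Generate a synthetic whole-slide mosaic
#'
#' Renders a grid of cores and stitches them (with their ground truth, shifted
#' to global coordinates) into one large image. The default 4 x 4 grid of
#' 4096-pixel cores yields a 16,384-squared slide, a desk-scale stand-in for
#' full scanner output; the tiling logic downstream is identical at any size.
#'
#' @param specs List of [core_spec()]s, length `nrow * ncol`.
#' @param grid_dim `c(nrow, ncol)` of the mosaic (default square).
#' @return An `ish_slide`: `image` ([ish_image]), `points` (global-coordinate
#'   truth with `core_id`), `cores` (tibble of per-core offsets, prototypes
#'   and expected ratios), `masks` (offset [disk_mask]s).
#' @export
generate_slide <- function(specs, grid_dim = NULL) {
  n <- length(specs)
  if (n < 1) abort("need at least one core spec", class = "dq_param_error")
  if (is.null(grid_dim)) {
    g <- ceiling(sqrt(n)); grid_dim <- c(g, g)
  }
  size <- specs[[1]]$image_size
  if (!all(vapply(specs, function(s) s$image_size, numeric(1)) == size)) {
    abort("all cores in a slide must share image_size", class = "dq_param_error")
  }
  H <- grid_dim[1] * size; W <- grid_dim[2] * size
  slide <- array(as.raw(252), dim = c(H, W, 3))
  pts <- vector("list", n); cores <- vector("list", n); masks <- vector("list", n)
  for (i in seq_len(n)) {
    gy <- (i - 1) %/% grid_dim[2]; gx <- (i - 1) %% grid_dim[2]
    x0 <- gx * size; y0 <- gy * size
    truth <- generate_point_set(specs[[i]])
    img <- render_core(truth, specs[[i]])
    slide[(y0 + 1):(y0 + size), (x0 + 1):(x0 + size), ] <- img$pixels
    p <- truth$points
    p$x <- p$x + x0; p$y <- p$y + y0; p$core_id <- i
    pts[[i]] <- p
    masks[[i]] <- disk_mask(truth$mask$cx + x0, truth$mask$cy + y0,
                            truth$mask$radius, W, H)
    cores[[i]] <- tibble(core_id = i, x0 = x0, y0 = y0,
                         prototype = specs[[i]]$prototype,
                         expected_global_ratio = truth$expected_global_ratio)
  }
  structure(list(image = ish_image(slide), points = bind_rows(pts),
                 cores = bind_rows(cores), masks = masks),
            class = "ish_slide")
}

#' Build the specs of a synthetic study cohort
#'
#' Produces core specifications mixing all six prototypes with realistic
#' per-core variation: tumour purity (the fraction of tumour cells carrying
#' the prototype genotype, the rest being benign two-copy cells), sectioning
#' loss, and cellularity each jitter around their defaults, so the cohort
#' forms a continuum in feature space rather than six point clusters, as
#' real tissue cohorts do.
#'
#' @param n_per_prototype Cores per prototype (default 12, i.e. 72 cores).
#' @param seed Integer seed.
#' @param image_size Canvas side length passed to [core_spec()].
#' @return List with `specs` (list of `ish_core_spec`) and `info` (tibble
#'   `core_id`, `prototype`, `purity`).
#' @export
cohort_specs <- function(n_per_prototype = 12, seed = 1, image_size = 4096) {
  protos <- core_prototypes()
  withr::with_seed(seed, {
    specs <- list(); info <- list(); k <- 0
    for (p in protos) for (s in seq_len(n_per_prototype)) {
      k <- k + 1
      purity <- runif(1, 0.60, 0.95)
      # homozygous cores span stronger benign contamination, bridging the
      # ratio continuum between full loss and hemizygous-like cores
      if (p == "HOMOZYGOUS_DELETION") purity <- runif(1, 0.45, 0.95)
      loss <- runif(1, 0.10, 0.20)
      cmul <- switch(p, CELLULAR_HET_HOMOGENEOUS_GENOTYPE = 1.35,
                     CELLULAR_HET_HETEROGENEOUS_GENOTYPE = 1.55, 1)
      ncl <- round(runif(1, 380, 460) * cmul * (image_size / 4096)^2)
      regions <- switch(p,
        NON_DELETION = list(list(copies = 2, probs = 1)),
        HEMIZYGOUS_DELETION = list(list(copies = c(1, 2),
                                        probs = c(purity, 1 - purity))),
        HOMOZYGOUS_DELETION = list(list(copies = c(0, 2),
                                        probs = c(purity, 1 - purity)),
                                   list(copies = 2, probs = 1)),
        CELLULAR_HET_HOMOGENEOUS_GENOTYPE = list(list(copies = 2, probs = 1)),
        CELLULAR_HET_HETEROGENEOUS_GENOTYPE = {
          pm <- runif(1, 0.10, 0.30)
          list(list(copies = c(0, 2), probs = c(pm, 1 - pm)))
        },
        INTRATUMOUR_HET = list(list(copies = 2, probs = 1),
                               list(copies = c(0, 2),
                                    probs = c(purity, 1 - purity))))
      split <- if (p == "INTRATUMOUR_HET") runif(1, 0.50, 0.68) else 0.5
      specs[[k]] <- core_spec(p, image_size = image_size, n_cells = ncl,
                              signal_loss_prob = loss, regions = regions,
                              split_frac = split, seed = sample.int(2^30, 1))
      info[[k]] <- tibble(core_id = k, prototype = p, purity = purity)
    }
    list(specs = specs, info = bind_rows(info))
  })
}

#' Generate a balanced annotated training set
#'
#' Renders synthetic cores with boosted colocalization and stain densities so
#' all five signal classes are abundant, runs the signal detector on them, and
#' transfers the planted labels to the matched detections (within 3 px), so
#' training examples carry the same localization and radius-estimation noise
#' the classifier will see at prediction time. Cell stains, which are diffuse
#' blobs rather than dot detections, are annotated at their planted positions.
#' A balanced sample of `crops_per_class` annotations per class is returned.
#'
#' @param crops_per_class Annotations per class (default 150; >= 10 required).
#' @param seed Integer seed.
#' @param specs Optional list of [core_spec()]s to draw from; the default is
#'   two non-deletion cores tuned for class abundance.
#' @param params [detection_params()] used for the detection pass.
#' @return An `ish_training_set`: `annotations` (tibble `image`, `x`, `y`,
#'   `radius`, `label`) and `images` (named list of rendered [ish_image]s).
#' @export
generate_training_set <- function(crops_per_class = 150, seed = 1, specs = NULL,
                                  params = detection_params()) {
  if (crops_per_class < 10) {
    abort("crops_per_class must be >= 10", class = "dq_param_error")
  }
  if (is.null(specs)) {
    specs <- list(
      core_spec("NON_DELETION", colocalization_prob = 0.45,
                stain_density = 4e-5, seed = seed * 2 + 11),
      core_spec("NON_DELETION", colocalization_prob = 0.45,
                stain_density = 4e-5, seed = seed * 2 + 12)
    )
  }
  truths <- lapply(specs, generate_point_set)
  images <- lapply(seq_along(specs), function(i) render_core(truths[[i]], specs[[i]]))
  names(images) <- paste0("core", seq_along(images))
  ann <- bind_rows(lapply(seq_along(truths), function(i) {
    tp <- truths[[i]]$points
    det <- detect_signals(images[[i]], truths[[i]]$mask, params)
    dots <- tp[tp$true_label != "CELL_STAIN", ]
    j <- cpp_nearest_unused(det$x, det$y, dots$x, dots$y)
    d <- sqrt((dots$x[j] - det$x)^2 + (dots$y[j] - det$y)^2)
    matched <- !is.na(j) & d <= 3
    stains <- tp[tp$true_label == "CELL_STAIN", ]
    bind_rows(
      tibble(image = paste0("core", i), x = det$x[matched], y = det$y[matched],
             radius = det$radius[matched], label = dots$true_label[j[matched]]),
      tibble(image = paste0("core", i), x = stains$x, y = stains$y,
             radius = stains$radius, label = stains$true_label)
    )
  }))
  picked <- withr::with_seed(seed, {
    bind_rows(lapply(signal_classes(), function(cl) {
      pool <- ann[ann$label == cl, ]
      if (nrow(pool) < crops_per_class) {
        abort(sprintf("class %s unreachable: only %d candidates for %d crops",
                      cl, nrow(pool), crops_per_class), class = "dq_data_error")
      }
      pool[sample.int(nrow(pool), crops_per_class), ]
    }))
  })
  structure(list(annotations = picked, images = images),
            class = "ish_training_set")
}
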