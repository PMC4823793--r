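#' Parameters of the randomized local statistics
#'
#' @param n_random Number of uniform random points per core (default 300).
#' @param radius Neighbourhood radius in pixels (default 60, chosen so the
#'   neighbourhood includes at least one adjacent cell at the 4096-pixel
#'   working scale).
#' @param seed Integer seed for the random draws.
#' @return A `dq_het_params`.
#' @export
heterogeneity_params <- function(n_random = 300, radius = 60, seed = 1) {
  if (n_random < 1) abort("n_random must be >= 1", class = "dq_param_error")
  if (radius <= 0) abort("radius must be > 0", class = "dq_param_error")
  structure(list(n_random = as.integer(n_random), radius = radius,
                 seed = as.integer(seed)),
            class = "dq_het_params")
}

# CEP-carrying points under the mixed-signal policy
cep_carriers <- function(points, mixed_policy) {
  keep <- points$label == "CEP"
  if (mixed_policy == "count_both") keep <- keep | points$label == "GENE_CEP_MIXED"
  points[keep, , drop = FALSE]
}

gene_carriers <- function(points, mixed_policy) {
  keep <- points$label == "GENE"
  if (mixed_policy == "count_both") keep <- keep | points$label == "GENE_CEP_MIXED"
  points[keep, , drop = FALSE]
}

#' Sample CEP anchor points for the randomized local statistics
#'
#' Draws `n_random` points uniformly over the tissue region and substitutes
#' each by the coordinate of its closest CEP signal, sampling without
#' replacement: a CEP point already used as an anchor is removed from further
#' snapping, so no CEP anchors a neighbourhood twice. When fewer CEP points
#' exist than `n_random`, every CEP becomes an anchor.
#'
#' @param points Labeled signal tibble.
#' @param mask Tissue mask ([ish_mask] or [disk_mask]).
#' @param params A [heterogeneity_params]; its `seed` drives the draws.
#' @param mixed_policy Whether colocalized mixed signals count as CEP carriers
#'   (`"count_both"`, default) or not (`"exclude"`).
#' @return Tibble of anchors (`anchor_id`, `x`, `y`).
#' @export
sample_anchor_points <- function(points, mask, params = heterogeneity_params(),
                                 mixed_policy = c("count_both", "exclude")) {
  mixed_policy <- match.arg(mixed_policy)
  ceps <- cep_carriers(points, mixed_policy)
  if (nrow(ceps) == 0) {
    abort("no CEP-labeled signals to anchor neighbourhoods on",
          class = "dq_data_error")
  }
  if (nrow(ceps) <= params$n_random) {
    anchors <- ceps
  } else {
    draws <- withr::with_seed(params$seed, uniform_in_mask(mask, params$n_random))
    idx <- cpp_nearest_unused(draws[, 1], draws[, 2], ceps$x, ceps$y)
    anchors <- ceps[idx, , drop = FALSE]
  }
  tibble(anchor_id = seq_len(nrow(anchors)), x = anchors$x, y = anchors$y)
}

#' Randomized local ratio and density distributions
#'
#' For each anchor, counts the gene and CEP signals within Euclidean distance
#' `radius` (the anchor itself is included in the CEP count). The local ratio
#' is genes / CEPs; the local density is their total. The mixed-signal policy
#' is applied as in [global_ratio()].
#'
#' @param points Labeled signal tibble.
#' @param anchors Anchor tibble from [sample_anchor_points()].
#' @param params A [heterogeneity_params] (supplies `radius`).
#' @param mixed_policy See [sample_anchor_points()].
#' @return Tibble of local samples: `anchor_id`, `x`, `y`, `local_gene_count`,
#'   `local_cep_count`, `local_ratio`, `local_density`.
#' @export
compute_rlr_rld <- function(points, anchors, params = heterogeneity_params(),
                            mixed_policy = c("count_both", "exclude")) {
  mixed_policy <- match.arg(mixed_policy)
  genes <- gene_carriers(points, mixed_policy)
  ceps <- cep_carriers(points, mixed_policy)
  ng <- cpp_disk_counts(anchors$x, anchors$y, genes$x, genes$y, params$radius)
  nc <- cpp_disk_counts(anchors$x, anchors$y, ceps$x, ceps$y, params$radius)
  tibble(anchor_id = anchors$anchor_id, x = anchors$x, y = anchors$y,
         local_gene_count = ng, local_cep_count = nc,
         local_ratio = ng / nc, local_density = ng + nc)
}

#' Summarize RLR/RLD distributions into the 6-dimensional core feature vector
#'
#' Extracts mean, median and standard error of the mean from the local-ratio
#' and local-density distributions (3 x 2 = 6 dimensions). The SEM uses the
#' sample SD (n - 1 denominator) divided by the square root of the sample
#' count.
#'
#' @param local_samples Tibble from [compute_rlr_rld()].
#' @return One-row tibble: `rlr_mean`, `rlr_median`, `rlr_sem`, `rld_mean`,
#'   `rld_median`, `rld_sem`.
#' @export
summarize_features <- function(local_samples) {
  if (nrow(local_samples) < 2) {
    abort("need at least 2 local samples to summarize", class = "dq_data_error")
  }
  rlr <- local_samples$local_ratio
  rld <- local_samples$local_density
  tibble(rlr_mean = mean(rlr), rlr_median = median(rlr),
         rlr_sem = sd(rlr) / sqrt(length(rlr)),
         rld_mean = mean(rld), rld_median = median(rld),
         rld_sem = sd(rld) / sqrt(length(rld)))
}

feature_cols <- c("rlr_mean", "rlr_median", "rlr_sem",
                  "rld_mean", "rld_median", "rld_sem")

#' Embed per-core feature vectors into two dimensions by PCA
#'
#' Features are z-scored per dimension (the six summary statistics live on
#' incommensurate scales) and projected onto the top two principal
#' components. Component signs are fixed so the largest-magnitude loading of
#' each component is positive. Constant feature columns are dropped with a
#' warning.
#'
#' @param features Tibble with one row per core: the six columns named in
#'   `rlr_mean`, ..., `rld_sem`, plus an optional `core_id` column.
#' @return An `ish_embedding`: coords (tibble of `core_id`, `PC1`, `PC2`),
#'   `loadings` (features x 2), `explained_variance` (proportions),
#'   `standardization` (per-feature mean/sd).
#' @export
embed_pca <- function(features) {
  if (nrow(features) < 3) abort("need >= 3 cores for PCA", class = "dq_data_error")
  core_id <- if ("core_id" %in% names(features)) features$core_id else seq_len(nrow(features))
  X <- as.matrix(features[, intersect(feature_cols, names(features)), drop = FALSE])
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    warn(paste0("dropping constant feature column(s): ",
                paste(colnames(X)[sds == 0], collapse = ", ")))
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  mus <- colMeans(X)
  Z <- scale(X, center = mus, scale = sds)
  pr <- prcomp(Z, center = FALSE, scale. = FALSE)
  k <- min(2, ncol(pr$rotation))
  load <- pr$rotation[, 1:k, drop = FALSE]
  for (j in 1:k) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  coords <- Z %*% load
  structure(list(
    coords = tibble(core_id = core_id, PC1 = coords[, 1],
                    PC2 = if (k > 1) coords[, 2] else 0),
    loadings = load,
    explained_variance = (pr$sdev^2 / sum(pr$sdev^2))[1:k],
    standardization = list(mean = mus, sd = sds)
  ), class = "ish_embedding")
}

#' Project new feature vectors with a fitted embedding
#'
#' Applies the stored per-feature standardization and loadings of an existing
#' [embed_pca()] fit, so repeated measurements of a core land in the same
#' subspace as the cohort.
#'
#' @param embedding An `ish_embedding`.
#' @param features Feature tibble (same columns as used for the fit).
#' @return Tibble with `PC1`, `PC2`.
#' @export
project_features <- function(embedding, features) {
  st <- embedding$standardization
  X <- as.matrix(features[, names(st$mean), drop = FALSE])
  Z <- scale(X, center = st$mean, scale = st$sd)
  coords <- Z %*% embedding$loadings
  tibble(PC1 = coords[, 1],
         PC2 = if (ncol(coords) > 1) coords[, 2] else 0)
}

# ---------------------------------------------------------------------------
# Gaussian mixture model with AIC model selection (full covariances, EM)
# ---------------------------------------------------------------------------

gmm_em_once <- function(X, k, init_assign, prior, max_iter = 300, tol = 1e-8) {
  fit <- cpp_gmm_em(X, as.integer(init_assign), as.integer(k), prior, 4.0,
                    as.integer(max_iter), tol)
  if (!isTRUE(fit$ok)) return(NULL)
  list(w = as.numeric(fit$w), mu = fit$mu, sig = fit$sig, ll = fit$ll,
       resp = fit$resp)
}

gmm_fit <- function(X, k, seed, n_restarts = 10) {
  if (k == 1) n_restarts <- 1   # deterministic fit
  best <- NULL
  prior <- cov(X) / k
  for (r in seq_len(n_restarts)) {
    fit <- withr::with_seed(seed + 1000L * r + k, {
      init <- if (k == 1) rep(1L, nrow(X)) else {
        km <- suppressWarnings(kmeans(X, centers = k, nstart = 1, iter.max = 50))
        km$cluster
      }
      gmm_em_once(X, k, init, prior)
    })
    if (!is.null(fit) && (is.null(best) || fit$ll > best$ll)) best <- fit
  }
  best
}

#' Fit a Gaussian mixture with a fixed component count
#'
#' Fits one full-covariance Gaussian mixture by EM (k-means initialization,
#' 10 seeded restarts). The three-component fit is the workhorse of the
#' subclass analysis: it recovers the homogeneous-deletion, homogeneous
#' non-deletion and heterogeneous classes in the embedding, with the
#' homogeneous-deletion component serving as the Mahalanobis reference.
#'
#' @param coords 2-D coordinates (matrix, tibble with `PC1`/`PC2`, or an
#'   `ish_embedding`).
#' @param k Number of components.
#' @param seed Integer seed for initialization.
#' @return An `ish_gmm`.
#' @export
fit_gmm <- function(coords, k, seed = 1) {
  X <- coords_matrix(coords)
  if (nrow(X) <= k) abort("need more points than components", class = "dq_data_error")
  fit <- gmm_fit(X, k, seed)
  if (is.null(fit)) abort("EM failed to converge", class = "dq_data_error")
  p <- (k - 1) + 2 * k + 3 * k
  aic_by_k <- rep(NA_real_, k)
  aic_by_k[k] <- 2 * p - 2 * fit$ll
  structure(list(k = k, weights = fit$w, means = fit$mu,
                 covariances = fit$sig, loglik = fit$ll,
                 aic = aic_by_k[k], aic_by_k = aic_by_k,
                 assignments = max.col(fit$resp), seed = seed),
            class = "ish_gmm")
}

#' Fit Gaussian mixtures and select the component count by AIC
#'
#' Fits full-covariance Gaussian mixture models by EM (k-means
#' initialization, 10 restarts, seeded) for every component count from 1 to
#' `k_max` and returns the model minimizing AIC = 2p - 2 log L, with
#' p = (k - 1) + 2k + 3k free parameters in two dimensions (weights, means,
#' covariances). Hard assignments are by maximum posterior responsibility.
#'
#' @param coords Matrix or tibble of 2-D embedding coordinates (`PC1`, `PC2`),
#'   or an `ish_embedding`.
#' @param k_max Largest component count scanned (default 5).
#' @param seed Integer seed for initialization.
#' @return An `ish_gmm` with fields `k`, `weights`, `means`, `covariances`,
#'   `loglik`, `aic`, `aic_by_k`, `assignments`, `seed`.
#' @export
select_k_by_aic <- function(coords, k_max = 5, seed = 1) {
  X <- coords_matrix(coords)
  if (nrow(X) <= k_max) {
    abort("need more points than k_max", class = "dq_data_error")
  }
  fits <- vector("list", k_max)
  aic <- rep(NA_real_, k_max)
  for (k in seq_len(k_max)) {
    fits[k] <- list(gmm_fit(X, k, seed))
    if (!is.null(fits[[k]])) {
      p <- (k - 1) + 2 * k + 3 * k
      aic[k] <- 2 * p - 2 * fits[[k]]$ll
    }
  }
  if (all(is.na(aic))) abort("EM failed to converge for every k", class = "dq_data_error")
  kbest <- which.min(aic)
  fit <- fits[[kbest]]
  structure(list(k = kbest, weights = fit$w, means = fit$mu,
                 covariances = fit$sig, loglik = fit$ll,
                 aic = aic[kbest], aic_by_k = aic,
                 assignments = max.col(fit$resp), seed = seed),
            class = "ish_gmm")
}

coords_matrix <- function(coords) {
  if (inherits(coords, "ish_embedding")) coords <- coords$coords
  if (is.data.frame(coords)) {
    as.matrix(coords[, c("PC1", "PC2")])
  } else {
    as.matrix(coords)
  }
}

#' @export
print.ish_gmm <- function(x, ...) {
  cat(sprintf("<ish_gmm> k = %d (AIC %.1f), weights: %s\n", x$k, x$aic,
              paste(sprintf("%.2f", x$weights), collapse = ", ")))
  invisible(x)
}

#' @method tidy ish_gmm
#' @export
tidy.ish_gmm <- function(x, ...) {
  tibble(component = seq_len(x$k), weight = x$weights,
         mean_1 = x$means[, 1], mean_2 = x$means[, 2],
         n_assigned = as.integer(table(factor(x$assignments, levels = seq_len(x$k)))))
}

#' @method glance ish_gmm
#' @export
glance.ish_gmm <- function(x, ...) {
  tibble(k = x$k, loglik = x$loglik, aic = x$aic, seed = x$seed)
}

#' Extract one component of a fitted mixture
#' @param model An `ish_gmm`.
#' @param index Component index.
#' @return List with `mean`, `cov`, `weight`.
#' @export
gmm_component <- function(model, index) {
  list(mean = model$means[index, ], cov = model$covariances[[index]],
       weight = model$weights[index])
}

#' Mahalanobis distances to a mixture component
#'
#' Computes d(x) = sqrt((x - mu)' Sigma^-1 (x - mu)) for every coordinate,
#' using the component's mean and covariance: the number of standard
#' deviations separating a core from the component centroid.
#'
#' @param coords 2-D coordinates (matrix, tibble or `ish_embedding`).
#' @param component A component from [gmm_component()] (any list with `mean`
#'   and `cov`).
#' @return Numeric vector of distances.
#' @export
mahalanobis_distances <- function(coords, component) {
  X <- coords_matrix(coords)
  ch <- tryCatch(chol(component$cov), error = function(e) NULL)
  if (is.null(ch)) {
    abort("component covariance is singular", class = "dq_data_error")
  }
  sqrt(mahalanobis(X, component$mean, component$cov))
}

#' Identify the homogeneous-deletion reference component
#'
#' Homogeneous deletion exhibits the lowest gene-to-CEP ratio, so the
#' reference component is the one whose member cores have the smallest mean
#' `rlr_mean`. Empty components are excluded; ties resolve to the lower
#' component index.
#'
#' @param model An `ish_gmm` with assignments.
#' @param features The per-core feature tibble the embedding was fitted on
#'   (row order must match).
#' @return Integer component index.
#' @export
identify_reference_component <- function(model, features) {
  means <- rep(NA_real_, model$k)
  for (j in seq_len(model$k)) {
    i <- which(model$assignments == j)
    if (length(i) > 0) means[j] <- mean(features$rlr_mean[i])
  }
  which.min(means)   # NA (empty) components never win; ties -> lower index
}

#' Perturbation ellipses over the randomization range
#'
#' Repeats the anchor-sampling / RLR-RLD / summary pipeline `reps` times per
#' core, cycling the number of random points through `n_range` (repetition i
#' uses n = n_range[1] + (i - 1) mod width and seed = base_seed + i), projects
#' every repetition with the cohort's fixed PCA, and summarizes each core's
#' repetition cloud as a 95% confidence ellipse (covariance eigen-axes scaled
#' by the chi-squared(2) 0.95 quantile).
#'
#' @param points_by_core Named list of labeled signal tibbles, one per core.
#' @param masks List of tissue masks aligned with `points_by_core`.
#' @param embedding The cohort `ish_embedding` (fixed projection).
#' @param radius Neighbourhood radius (pixels).
#' @param n_range Integer range of random-point counts, default `c(201, 300)`.
#' @param reps Repetitions per core (default 100).
#' @param base_seed Base seed; repetition i uses `base_seed + i`.
#' @param mixed_policy See [sample_anchor_points()].
#' @return Tibble with one row per core: `core_id`, `center_1`, `center_2`,
#'   `axis_major`, `axis_minor`, `orientation`, `area`, `n_reps`. The
#'   repetition clouds are attached as attribute `clouds`.
#' @export
perturbation_ellipses <- function(points_by_core, masks, embedding,
                                  radius = 60, n_range = c(201, 300),
                                  reps = 100, base_seed = 1,
                                  mixed_policy = "count_both") {
  if (reps < 2) abort("reps must be >= 2", class = "dq_param_error")
  width <- n_range[2] - n_range[1] + 1
  ids <- names(points_by_core) %||% as.character(seq_along(points_by_core))
  clouds <- vector("list", length(points_by_core))
  out <- vector("list", length(points_by_core))
  for (ci in seq_along(points_by_core)) {
    pts <- points_by_core[[ci]]
    feats <- lapply(seq_len(reps), function(i) {
      hp <- heterogeneity_params(
        n_random = n_range[1] + (i - 1) %% width,
        radius = radius, seed = base_seed + i)
      anchors <- sample_anchor_points(pts, masks[[ci]], hp, mixed_policy)
      summarize_features(compute_rlr_rld(pts, anchors, hp, mixed_policy))
    })
    proj <- as.matrix(project_features(embedding, bind_rows(feats)))
    ctr <- colMeans(proj)
    S <- cov(proj)
    e <- eigen(S, symmetric = TRUE)
    ax <- sqrt(pmax(e$values, 0) * qchisq(0.95, 2))
    clouds[[ci]] <- proj
    out[[ci]] <- tibble(core_id = ids[ci], center_1 = ctr[1], center_2 = ctr[2],
                        axis_major = ax[1], axis_minor = ax[2],
                        orientation = atan2(e$vectors[2, 1], e$vectors[1, 1]),
                        area = pi * ax[1] * ax[2], n_reps = reps)
  }
  res <- bind_rows(out)
  attr(res, "clouds") <- setNames(clouds, ids)
  res
}
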