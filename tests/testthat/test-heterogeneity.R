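test_that("anchor sampling exhausts, reproduces, and snaps to nearest unused CEP", {
  # exhaustion: fewer CEPs than n_random -> every CEP is an anchor
  few <- tibble::tibble(x = 1:5 * 10, y = rep(5, 5), label = "CEP")
  mask <- disk_mask(50, 50, 60, 100, 100)
  a <- sample_anchor_points(few, mask, heterogeneity_params(seed = 1))
  expect_equal(nrow(a), 5)
  expect_setequal(a$x, few$x)

  # reproducibility and distinctness on a dense CEP grid
  grid <- expand.grid(x = seq(20, 480, by = 15), y = seq(20, 480, by = 15))
  ceps <- tibble::tibble(x = grid$x, y = grid$y, label = "CEP")
  mask <- disk_mask(250, 250, 240, 500, 500)
  hp <- heterogeneity_params(n_random = 300, seed = 9)
  a1 <- sample_anchor_points(ceps, mask, hp)
  a2 <- sample_anchor_points(ceps, mask, hp)
  expect_equal(nrow(a1), 300)
  expect_identical(a1, a2)
  expect_equal(nrow(unique(a1[, c("x", "y")])), 300)

  # snapping equals brute-force sequential nearest-unused assignment
  draws <- withr::with_seed(hp$seed, dishquant:::uniform_in_mask(mask, 300))
  used <- rep(FALSE, nrow(ceps))
  want <- integer(300)
  for (i in 1:300) {
    d2 <- (ceps$x - draws[i, 1])^2 + (ceps$y - draws[i, 2])^2
    d2[used] <- Inf
    want[i] <- which.min(d2)
    used[want[i]] <- TRUE
  }
  expect_equal(a1$x, ceps$x[want])
  expect_equal(a1$y, ceps$y[want])

  expect_error(sample_anchor_points(tibble::tibble(x = 1, y = 1, label = "GENE"),
                                    mask, hp),
               class = "dq_data_error")
})

test_that("local ratio/density match the exhaustive disk-membership oracle", {
  # colocated pairs on a sparse lattice: each disk holds exactly one pair
  grid <- expand.grid(x = seq(100, 900, by = 200), y = seq(100, 900, by = 200))
  pts <- dplyr::bind_rows(
    tibble::tibble(x = grid$x, y = grid$y, label = "GENE"),
    tibble::tibble(x = grid$x + 2, y = grid$y, label = "CEP"))
  anchors <- tibble::tibble(anchor_id = seq_len(nrow(grid)),
                            x = grid$x + 2, y = grid$y)
  loc <- compute_rlr_rld(pts, anchors, heterogeneity_params(radius = 60))
  expect_true(all(loc$local_ratio == 1))
  expect_true(all(loc$local_density == 2))

  # CEP-only core: all ratios zero, anchor included in its own count
  ceponly <- tibble::tibble(x = grid$x, y = grid$y, label = "CEP")
  anch2 <- tibble::tibble(anchor_id = 1:2, x = grid$x[1:2], y = grid$y[1:2])
  loc2 <- compute_rlr_rld(ceponly, anch2, heterogeneity_params(radius = 60))
  expect_true(all(loc2$local_ratio == 0))
  expect_true(all(loc2$local_cep_count >= 1))

  # 100 random configurations against a plain double-loop oracle
  for (s in 1:100) {
    cfg <- withr::with_seed(s, {
      n <- sample(50:150, 1)
      list(p = tibble::tibble(
             x = runif(n, 0, 400), y = runif(n, 0, 400),
             label = sample(signal_classes(), n, replace = TRUE,
                            prob = c(0.3, 0.3, 0.1, 0.2, 0.1))),
           a = sample(1:15, 1), r = runif(1, 20, 80))
    })
    ceps <- cfg$p[cfg$p$label %in% c("CEP", "GENE_CEP_MIXED"), ]
    if (nrow(ceps) == 0) next
    na <- min(cfg$a, nrow(ceps))
    anchors <- tibble::tibble(anchor_id = seq_len(na),
                              x = ceps$x[seq_len(na)], y = ceps$y[seq_len(na)])
    loc <- compute_rlr_rld(cfg$p, anchors,
                           heterogeneity_params(radius = cfg$r))
    genes <- cfg$p[cfg$p$label %in% c("GENE", "GENE_CEP_MIXED"), ]
    for (i in seq_len(na)) {
      og <- sum((genes$x - anchors$x[i])^2 + (genes$y - anchors$y[i])^2 <= cfg$r^2)
      oc <- sum((ceps$x - anchors$x[i])^2 + (ceps$y - anchors$y[i])^2 <= cfg$r^2)
      expect_identical(loc$local_gene_count[i], og)
      expect_identical(loc$local_cep_count[i], oc)
    }
  }
})

test_that("feature summaries follow hand arithmetic", {
  mk <- function(rlr, rld) tibble::tibble(local_ratio = rlr, local_density = rld)
  f0 <- summarize_features(mk(rep(1, 10), rep(2, 10)))
  expect_equal(f0$rlr_mean, 1); expect_equal(f0$rlr_median, 1)
  expect_equal(f0$rlr_sem, 0)

  f1 <- summarize_features(mk(c(0, 0, 1, 1), c(1, 2, 3, 4)))
  expect_equal(f1$rlr_mean, 0.5)
  expect_equal(f1$rlr_median, 0.5)
  expect_equal(f1$rlr_sem, sqrt(1 / 3) / 2)

  # duplicating every sample: mean/median unchanged; the SEM shrinks by the
  # exact finite-n factor sqrt((n-1)/(2n-1)) (asymptotically 1/sqrt(2))
  f2 <- summarize_features(mk(rep(c(0, 0, 1, 1), 2), rep(c(1, 2, 3, 4), 2)))
  expect_equal(f2$rlr_mean, f1$rlr_mean)
  expect_equal(f2$rlr_median, f1$rlr_median)
  expect_equal(f2$rlr_sem, f1$rlr_sem * sqrt(3 / 7), tolerance = 1e-12)

  expect_error(summarize_features(mk(1, 1)), class = "dq_data_error")
})

test_that("PCA embedding matches an independent eigen-decomposition", {
  feats <- withr::with_seed(10, {
    tibble::tibble(rlr_mean = runif(20), rlr_median = runif(20),
                   rlr_sem = runif(20, 0, 0.1), rld_mean = runif(20, 2, 10),
                   rld_median = runif(20, 2, 10), rld_sem = runif(20, 0, 0.5))
  })
  emb <- embed_pca(feats)
  Z <- scale(as.matrix(feats))
  ev <- eigen(crossprod(Z) / (nrow(Z) - 1), symmetric = TRUE)
  V <- ev$vectors[, 1:2]
  for (j in 1:2) if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  ref <- Z %*% V
  expect_equal(emb$coords$PC1, ref[, 1], tolerance = 1e-8)
  expect_equal(emb$coords$PC2, ref[, 2], tolerance = 1e-8)
  expect_equal(sum(emb$explained_variance),
               sum(ev$values[1:2]) / sum(ev$values), tolerance = 1e-8)

  # rank-1 data: PC1 captures ~100% of variance
  f1 <- feats
  f1[] <- lapply(seq_along(f1), function(j) j * seq_len(20) / 20)
  expect_gt(embed_pca(f1)$explained_variance[1], 0.999)

  # permutation equivariance
  perm <- withr::with_seed(3, sample(20))
  emb_p <- embed_pca(feats[perm, ])
  expect_equal(emb_p$coords$PC1, emb$coords$PC1[perm], tolerance = 1e-8)

  # constant column dropped with a warning; projection consistency
  fc <- feats; fc$rld_sem <- 1
  expect_warning(embc <- embed_pca(fc), "constant")
  expect_equal(ncol(embc$loadings), 2)
  proj <- project_features(emb, feats)
  expect_equal(proj$PC1, emb$coords$PC1, tolerance = 1e-10)

  expect_error(embed_pca(feats[1:2, ]), class = "dq_data_error")
})

test_that("AIC selects the planted component count", {
  X3 <- withr::with_seed(21, {
    ctr <- matrix(c(0, 0, 8, 0, 4, 8), ncol = 2, byrow = TRUE)
    g <- sample(1:3, 71, replace = TRUE)
    ctr[g, ] + matrix(rnorm(142), ncol = 2)
  })
  m3 <- select_k_by_aic(X3, seed = 21)
  expect_equal(m3$k, 3)
  expect_equal(length(m3$aic_by_k), 5)       # scans exactly 1..5
  expect_equal(sum(m3$weights), 1, tolerance = 1e-8)
  expect_true(all(vapply(m3$covariances, function(S) {
    isTRUE(all.equal(S, t(S))) && all(eigen(S)$values > 0)
  }, logical(1))))

  X1 <- withr::with_seed(22, matrix(rnorm(200), ncol = 2))
  expect_equal(select_k_by_aic(X1, seed = 22)$k, 1)

  expect_error(select_k_by_aic(X1[1:4, ], k_max = 5, seed = 1),
               class = "dq_data_error")
})

test_that("the mixture fit agrees with mclust on well-separated data", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  X <- withr::with_seed(33, {
    ctr <- matrix(c(0, 0, 9, 0, 4, 9), ncol = 2, byrow = TRUE)
    g <- rep(1:3, c(25, 25, 21))
    ctr[g, ] + matrix(rnorm(142), ncol = 2)
  })
  ours <- fit_gmm(X, 3, seed = 1)
  ref <- suppressMessages(mclust::Mclust(X, G = 3, modelNames = "VVV",
                                         verbose = FALSE))
  ari <- mclust::adjustedRandIndex(ours$assignments, ref$classification)
  expect_equal(ari, 1)
  # our loglik sits just below the unpenalized ML optimum (the covariance
  # shrinkage trades a few percent of likelihood for stability) and the
  # component means coincide after matching clusters
  expect_lte(ours$loglik, ref$loglik + 1e-6)
  expect_lt(abs(ours$loglik - ref$loglik) / abs(ref$loglik), 0.05)
  ref_means <- t(ref$parameters$mean)
  match_i <- vapply(seq_len(3), function(j) {
    which.min(rowSums(sweep(ref_means, 2, ours$means[j, ])^2))
  }, integer(1))
  expect_equal(ours$means, ref_means[match_i, ],
               tolerance = 0.1, ignore_attr = TRUE)
})

test_that("Mahalanobis distances reduce to known special cases", {
  comp <- list(mean = c(1, 2), cov = diag(2))
  expect_equal(mahalanobis_distances(matrix(c(1, 2), 1), comp), 0)
  expect_equal(mahalanobis_distances(matrix(c(4, 6), 1), comp), 5)

  S <- withr::with_seed(5, { A <- matrix(rnorm(4), 2); A %*% t(A) + diag(2) })
  comp2 <- list(mean = c(-1, 3), cov = S)
  X <- withr::with_seed(6, matrix(rnorm(40), ncol = 2))
  want <- apply(X, 1, function(r) {
    d <- r - comp2$mean
    sqrt(drop(t(d) %*% solve(S) %*% d))
  })
  expect_equal(mahalanobis_distances(X, comp2), want, tolerance = 1e-10)

  sing <- list(mean = c(0, 0), cov = matrix(c(1, 1, 1, 1), 2))
  expect_error(mahalanobis_distances(X, sing), class = "dq_data_error")
})

test_that("the reference component is the lowest-ratio cluster", {
  model <- list(k = 3, assignments = rep(1:3, each = 4))
  class(model) <- "ish_gmm"
  feats <- tibble::tibble(rlr_mean = c(rep(0.9, 4), rep(0.2, 4), rep(0.6, 4)))
  expect_equal(identify_reference_component(model, feats), 2)

  # tie resolves to the lower component index
  feats2 <- tibble::tibble(rlr_mean = c(rep(0.2, 4), rep(0.2, 4), rep(0.6, 4)))
  expect_equal(identify_reference_component(model, feats2), 1)

  # empty components never win
  model$assignments <- rep(c(1, 3), each = 6)
  feats3 <- tibble::tibble(rlr_mean = rep(c(0.5, 0.8), each = 6))
  expect_equal(identify_reference_component(model, feats3), 1)
})

test_that("perturbation ellipses are deterministic and degenerate correctly", {
  tp <- truth_points("NON_DELETION", seed = 42)
  hp <- heterogeneity_params(seed = 5)
  f <- summarize_features(compute_rlr_rld(
    tp$points, sample_anchor_points(tp$points, tp$mask, hp), hp))
  emb <- embed_pca(dplyr::bind_rows(f, f * 1.01, f * 0.99))

  e1 <- perturbation_ellipses(list(tp$points), list(tp$mask), emb,
                              reps = 8, base_seed = 7)
  e2 <- perturbation_ellipses(list(tp$points), list(tp$mask), emb,
                              reps = 8, base_seed = 7)
  expect_identical(e1, e2)
  expect_equal(e1$n_reps, 8)

  # two identical repetitions (same n, same seed) give a zero-area cloud
  anchors <- sample_anchor_points(tp$points, tp$mask,
                                  heterogeneity_params(n_random = 250, seed = 4))
  ff <- summarize_features(compute_rlr_rld(tp$points, anchors,
                                           heterogeneity_params(radius = 60)))
  cloud <- as.matrix(project_features(emb, dplyr::bind_rows(ff, ff)))
  expect_equal(unname(diag(stats::cov(cloud))), c(0, 0))
  expect_error(perturbation_ellipses(list(tp$points), list(tp$mask), emb,
                                     reps = 1, base_seed = 1),
               class = "dq_param_error")
})

test_that("homogeneous cores have smaller perturbation ellipses than ITH cores", {
  # the cohort embedding is fitted once (as in a real analysis) and the
  # repetition clouds of fresh cores are projected into it
  ch <- cohort_specs(2, seed = 99)
  feats <- dplyr::bind_rows(lapply(seq_along(ch$specs), function(k) {
    tr <- generate_point_set(ch$specs[[k]])
    p <- dplyr::mutate(tr$points, label = true_label)
    hp <- heterogeneity_params(seed = 990 + k)
    summarize_features(compute_rlr_rld(p, sample_anchor_points(p, tr$mask, hp),
                                       hp))
  }))
  emb <- embed_pca(feats)
  areas <- vapply(1:10, function(s) {
    tn <- truth_points("NON_DELETION", seed = 7000 + s)
    ti <- truth_points("INTRATUMOUR_HET", seed = 8000 + s)
    ell <- perturbation_ellipses(list(tn$points, ti$points),
                                 list(tn$mask, ti$mask), emb,
                                 reps = 60, base_seed = s * 101)
    ell$area[1:2]
  }, numeric(2))
  # a homogeneous core's ellipse is typically at most half an ITH core's,
  # and smaller in clear majority of paired draws
  expect_lte(median(areas[1, ] / areas[2, ]), 0.5)
  expect_gte(sum(areas[1, ] < areas[2, ]), 8)
  expect_lt(mean(areas[1, ]), mean(areas[2, ]))
})
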