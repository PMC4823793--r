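# feature layout shared by training and prediction; bump the version whenever
# the layout changes so stale models refuse to classify
dq_feature_names <- c("r_mean", "g_mean", "b_mean", "r_sd", "g_sd", "b_sd",
                      "lab_a_mean", "lab_b_mean", "radius", "ring_contrast",
                      "lum_mean", "edge_gradient", "sat_mean", "lum_sd")
dq_feature_version <- "dq-features-1"

#' Extract per-signal appearance features
#'
#' Computes a 14-dimensional appearance vector for each signal: mean and SD of
#' R, G, B inside the signal disk; mean CIELAB a* and b* chroma; the disk
#' radius; the luminance contrast between a surrounding ring and the disk;
#' mean disk luminance; mean gradient magnitude along the disk boundary; mean
#' HSV saturation; and the in-disk luminance SD. Disk and ring are clipped at
#' image borders. The vector is deterministic in (image, point).
#'
#' @param image An [ish_image].
#' @param points Signal tibble with `x`, `y`, `radius`.
#' @return Tibble of features, one row per signal.
#' @export
extract_features <- function(image, points) {
  d <- dim(image$pixels)
  if (nrow(points) == 0) {
    m <- matrix(numeric(0), ncol = length(dq_feature_names))
  } else {
    m <- cpp_extract_features(image$pixels, d[1], d[2],
                              points$x, points$y, points$radius)
  }
  colnames(m) <- dq_feature_names
  as_tibble(m)
}

# stratified k-fold assignment, deterministic under the given seed
stratified_folds <- function(labels, k, seed) {
  withr::with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      i <- which(labels == cl)
      fold[i] <- sample(rep_len(seq_len(k), length(i)))
    }
    fold
  })
}

#' Train the five-class signal classifier
#'
#' Fits an RBF-kernel support vector machine (one-vs-one multiclass) on
#' annotated signals. Hyperparameters are chosen by grid search inside
#' stratified 5-fold cross-validation: cost over \{0.1, 1, 10, 100\} and
#' kernel width over \eqn{2^{-4} \ldots 2^{2}} times the median heuristic
#' (inverse median squared pairwise distance of standardized features). Class
#' imbalance is handled by inverse-frequency class weights. Ties in mean CV
#' accuracy resolve to the smaller cost, then the smaller gamma.
#'
#' @param annotations Tibble with columns `image` (name/index into `images`),
#'   `x`, `y`, `radius`, `label`; or an `ish_training_set` from
#'   [generate_training_set()] (then `images` may be omitted).
#' @param images Named list of [ish_image] objects referenced by
#'   `annotations$image`.
#' @param seed Integer seed controlling fold assignment.
#' @return An `ish_classifier` with fields `model`, `feature_spec`,
#'   `cv_report` (5 folds + mean), `classes`, `cost`, `gamma`, `seed`.
#' @export
train_classifier <- function(annotations, images = NULL, seed = 1) {
  if (inherits(annotations, "ish_training_set")) {
    images <- annotations$images
    annotations <- annotations$annotations
  }
  lab <- as.character(annotations$label)
  missing_cls <- setdiff(signal_classes(), unique(lab))
  if (length(missing_cls) > 0) {
    abort(paste0("training set lacks classes: ", paste(missing_cls, collapse = ", ")),
          class = "dq_data_error")
  }
  tab <- table(lab)
  if (any(tab < 10)) {
    abort(paste0("need >= 10 examples per class; short: ",
                 paste(names(tab)[tab < 10], collapse = ", ")),
          class = "dq_data_error")
  }
  X <- matrix(NA_real_, nrow(annotations), length(dq_feature_names),
              dimnames = list(NULL, dq_feature_names))
  for (im in unique(annotations$image)) {
    i <- which(annotations$image == im)
    X[i, ] <- as.matrix(extract_features(images[[im]], annotations[i, ]))
  }
  y <- factor(lab, levels = signal_classes())
  w <- as.numeric(length(y) / (length(levels(y)) * table(y)))
  names(w) <- levels(y)

  Xs <- scale(X)
  Xs[!is.finite(Xs)] <- 0
  d2 <- withr::with_seed(seed, {
    i <- sample(nrow(Xs), min(500, nrow(Xs)))
    as.numeric(dist(Xs[i, ]))^2
  })
  gamma_base <- 1 / max(median(d2), 1e-8)
  costs <- c(0.1, 1, 10, 100)
  gammas <- gamma_base * 2^(-4:2)
  fold <- stratified_folds(lab, 5, seed)

  cv_acc <- function(cost, gamma) {
    acc <- numeric(5)
    for (f in 1:5) {
      tr <- fold != f
      fit <- e1071::svm(X[tr, , drop = FALSE], y[tr], kernel = "radial",
                        cost = cost, gamma = gamma, class.weights = w,
                        scale = TRUE)
      acc[f] <- mean(predict(fit, X[!tr, , drop = FALSE]) == y[!tr])
    }
    acc
  }
  grid <- expand.grid(cost = costs, gamma = gammas)
  accs <- lapply(seq_len(nrow(grid)), function(i) cv_acc(grid$cost[i], grid$gamma[i]))
  means <- vapply(accs, mean, numeric(1))
  ord <- order(-means, grid$cost, grid$gamma)
  best <- ord[1]

  model <- e1071::svm(X, y, kernel = "radial", cost = grid$cost[best],
                      gamma = grid$gamma[best], class.weights = w,
                      scale = TRUE, probability = TRUE)
  structure(list(
    model = model,
    feature_spec = list(names = dq_feature_names, version = dq_feature_version),
    cv_report = tibble(fold = 1:5, accuracy = accs[[best]]),
    classes = signal_classes(),
    cost = grid$cost[best], gamma = grid$gamma[best],
    class_weights = w, seed = seed,
    package_version = as.character(utils::packageVersion("dishquant"))
  ), class = "ish_classifier")
}

#' @export
print.ish_classifier <- function(x, ...) {
  cat(sprintf("<ish_classifier> RBF SVM, cost=%g gamma=%.4g, mean CV accuracy %.3f\n",
              x$cost, x$gamma, mean(x$cv_report$accuracy)))
  invisible(x)
}

#' @method tidy ish_classifier
#' @export
tidy.ish_classifier <- function(x, ...) x$cv_report

#' @method glance ish_classifier
#' @export
glance.ish_classifier <- function(x, ...) {
  tibble(mean_cv_accuracy = mean(x$cv_report$accuracy),
         cost = x$cost, gamma = x$gamma,
         n_support_vectors = nrow(x$model$SV))
}

#' Classify detected signals
#'
#' Extracts appearance features for each detection and applies the trained
#' SVM. Every point receives a `label` (one of [signal_classes()]) and a
#' `label_score` in `[0, 1]` (maximum posterior class probability from the
#' SVM's Platt calibration).
#'
#' @param classifier An `ish_classifier`.
#' @param image The [ish_image] the points were detected in.
#' @param points Signal tibble with `x`, `y`, `radius`.
#' @return `points` with `label` and `label_score` columns filled.
#' @export
classify_signals <- function(classifier, image, points) {
  if (!identical(classifier$feature_spec$names, dq_feature_names) ||
      !identical(classifier$feature_spec$version, dq_feature_version)) {
    abort("classifier feature_spec does not match this package's feature layout",
          class = "dq_model_error")
  }
  if (nrow(points) == 0) {
    return(mutate(points, label = character(0), label_score = numeric(0)))
  }
  X <- as.matrix(extract_features(image, points))
  pred <- predict(classifier$model, X, probability = TRUE)
  pr <- attr(pred, "probabilities")
  points$label <- as.character(pred)
  points$label_score <- apply(pr, 1, max)
  points
}
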