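#' Global gene-to-CEP ratio of a tissue region
#'
#' The global ratio is the division of all gene signals by all CEP signals in
#' a region, scored without identifying individual nuclei. Only `GENE`, `CEP`
#' and `GENE_CEP_MIXED` labels enter the counts; `NOISE` and `CELL_STAIN` are
#' ignored. Under the default `count_both` policy a colocalized mixed signal
#' contributes one gene and one CEP to the respective totals (it contains one
#' of each); under `exclude` mixed signals are dropped from both.
#'
#' @param points Labeled signal tibble (a `label` column is required).
#' @param mixed_policy `"count_both"` (default) or `"exclude"`.
#' @return One-row tibble: `gene_count`, `cep_count`, `mixed_count`,
#'   `mixed_policy`, `global_ratio` (`NA` when the denominator is zero) and
#'   `ratio_defined`.
#' @export
global_ratio <- function(points, mixed_policy = c("count_both", "exclude")) {
  mixed_policy <- match.arg(mixed_policy)
  if (!"label" %in% names(points)) {
    abort("points must carry a 'label' column", class = "dq_data_error")
  }
  g <- sum(points$label == "GENE")
  c_ <- sum(points$label == "CEP")
  m <- sum(points$label == "GENE_CEP_MIXED")
  num <- if (mixed_policy == "count_both") g + m else g
  den <- if (mixed_policy == "count_both") c_ + m else c_
  tibble(gene_count = g, cep_count = c_, mixed_count = m,
         mixed_policy = mixed_policy,
         global_ratio = if (den > 0) num / den else NA_real_,
         ratio_defined = den > 0)
}

#' Copy-number thresholds
#'
#' Deletion assays call `DELETION` when the ratio is less than or equal to
#' the deletion threshold (60% by default, boundary inclusive); amplification
#' assays call `AMPLIFICATION` when the ratio is greater than or equal to the
#' amplification threshold (2.0 by default).
#'
#' @param deletion_threshold Default 0.60.
#' @param amplification_threshold Default 2.0.
#' @param direction `"deletion_assay"` or `"amplification_assay"`.
#' @return A `dq_threshold_config`.
#' @export
threshold_config <- function(deletion_threshold = 0.60,
                             amplification_threshold = 2.0,
                             direction = c("deletion_assay", "amplification_assay")) {
  direction <- match.arg(direction)
  if (!(deletion_threshold < amplification_threshold)) {
    abort("deletion_threshold must be < amplification_threshold",
          class = "dq_param_error")
  }
  structure(list(deletion_threshold = deletion_threshold,
                 amplification_threshold = amplification_threshold,
                 direction = direction),
            class = "dq_threshold_config")
}

#' Call copy-number status from a ratio score
#'
#' @param score A one- or multi-row tibble from [global_ratio()] (any tibble
#'   with a `global_ratio` column works).
#' @param config A [threshold_config].
#' @return `score` with `status` and `threshold_used` columns appended.
#' @export
call_status <- function(score, config = threshold_config()) {
  r <- score$global_ratio
  if (any(!is.finite(r))) {
    abort("global ratio is undefined (zero denominator); no status call",
          class = "dq_data_error")
  }
  if (config$direction == "deletion_assay") {
    status <- ifelse(r <= config$deletion_threshold, "DELETION", "NORMAL")
    thr <- config$deletion_threshold
  } else {
    status <- ifelse(r >= config$amplification_threshold, "AMPLIFICATION", "NORMAL")
    thr <- config$amplification_threshold
  }
  mutate(score, status = status, threshold_used = thr)
}

# rank-statistic AUC (midranks handle ties); direction "higher" means larger
# scores indicate the positive class
auc_rank <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC analysis with bootstrap confidence interval
#'
#' Computes the ROC curve and its AUC for continuous prediction scores against
#' binary reference labels, a 95% percentile-bootstrap confidence interval
#' over case-resampled replicates, and the operating threshold that optimizes
#' the chosen criterion (Youden's J, the equal-cost slope rule, by default;
#' alternatively the point closest to (0, 1)). The AUC is computed as the
#' rank statistic (Mann-Whitney), which equals the trapezoidal area under the
#' empirical curve.
#'
#' @param scores Numeric prediction scores (e.g. global ratios).
#' @param labels Binary reference labels (0/1, logical, or 2-level factor).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @param criterion `"youden"` or `"closest_topleft"`.
#' @param direction `"auto"` (orient so AUC >= 0.5), `"higher"` (larger score
#'   = positive) or `"lower"` (smaller score = positive, e.g. deletion ratios).
#' @return An `ish_roc` object; see [tidy()] for the curve and [glance()] for
#'   the one-row summary.
#' @export
roc_analysis <- function(scores, labels, n_boot = 1000, seed = 1,
                         criterion = c("youden", "closest_topleft"),
                         direction = c("auto", "higher", "lower")) {
  criterion <- match.arg(criterion)
  direction <- match.arg(direction)
  if (length(scores) != length(labels)) {
    abort("scores and labels must have equal length", class = "dq_param_error")
  }
  y <- if (is.factor(labels)) as.integer(labels) - 1L else as.integer(labels != 0)
  if (length(unique(y)) < 2) {
    abort("labels must contain both classes", class = "dq_data_error")
  }
  if (direction == "auto") {
    direction <- if (auc_rank(scores, y) >= 0.5) "higher" else "lower"
  }
  s <- if (direction == "higher") scores else -scores
  auc <- auc_rank(s, y)

  # empirical curve over the cuts "positive if s >= c", c at unique values
  us <- sort(unique(s), decreasing = TRUE)
  tp <- vapply(us, function(c) sum(s >= c & y == 1), numeric(1))
  fp <- vapply(us, function(c) sum(s >= c & y == 0), numeric(1))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  curve <- tibble(
    fpr = c(0, fp / n0), tpr = c(0, tp / n1),
    threshold = c(if (direction == "higher") Inf else -Inf,
                  if (direction == "higher") us else -us)
  )
  cand <- curve[-1, ]
  crit <- if (criterion == "youden") {
    cand$tpr - cand$fpr
  } else {
    -(cand$fpr^2 + (1 - cand$tpr)^2)
  }
  best <- which(crit == max(crit))
  best <- best[which.min(cand$fpr[best])]
  opt_thr <- cand$threshold[best]
  pred <- if (direction == "higher") scores >= opt_thr else scores <= opt_thr
  acc <- mean((pred & y == 1) | (!pred & y == 0))

  boot <- withr::with_seed(seed, {
    n <- length(s)
    vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[i])) < 2) return(NA_real_)
      auc_rank(s[i], y[i])
    }, numeric(1))
  })
  ci <- unname(quantile(boot, c(0.025, 0.975), na.rm = TRUE))

  structure(list(auc = auc, auc_ci_low = ci[1], auc_ci_high = ci[2],
                 optimal_threshold = opt_thr, accuracy_at_threshold = acc,
                 curve = curve, direction = direction, criterion = criterion,
                 n_boot = n_boot, seed = seed, n = length(scores)),
            class = "ish_roc")
}

#' @export
print.ish_roc <- function(x, ...) {
  cat(sprintf("<ish_roc> AUC %.3f [%.3f, %.3f], optimal threshold %.4g (%s), accuracy %.3f\n",
              x$auc, x$auc_ci_low, x$auc_ci_high, x$optimal_threshold,
              x$criterion, x$accuracy_at_threshold))
  invisible(x)
}

#' @method tidy ish_roc
#' @export
tidy.ish_roc <- function(x, ...) x$curve

#' @method glance ish_roc
#' @export
glance.ish_roc <- function(x, ...) {
  tibble(auc = x$auc, auc_ci_low = x$auc_ci_low, auc_ci_high = x$auc_ci_high,
         optimal_threshold = x$optimal_threshold,
         accuracy_at_threshold = x$accuracy_at_threshold,
         n = x$n, n_boot = x$n_boot)
}
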