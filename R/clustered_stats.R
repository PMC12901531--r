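#' @title Inference for clustered matched-pair classifier evaluation
#' @description Segments nested in subjects violate the independence
#'   assumptions of the usual ROC and McNemar machinery. This layer provides
#'   the clustered ROC AUC (Mann-Whitney point estimate with a
#'   components-of-placement-values variance that respects clustering), AUC
#'   percentage differences with per-repetition Z-tests combined by
#'   Bonferroni, a combined 5x2-CV F-test on cluster-robust marginal success
#'   probabilities, and Cramer's V.
#' @name clustered-stats
NULL

# Mann-Whitney AUC, ties score 1/2
auc_mann_whitney <- function(prob, labels) {
  pos <- prob[labels == 1]
  neg <- prob[labels == 0]
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Clustered ROC AUC with cluster-aware standard error
#'
#' Point estimate: the Mann-Whitney statistic over all (positive, negative)
#' record pairs, ties scoring 1/2. Default SE: the components method for
#' clustered ROC data — per-cluster sums of placement values, with the
#' cross-component covariance within cluster; it reduces exactly to the
#' unclustered component variance (sample variances of placement values over
#' n1, n0) when every cluster holds a single record. `se_method =
#' "jackknife"` instead deletes one cluster at a time and uses the
#' pseudovalue variance.
#'
#' @param probabilities predicted probabilities (or any score).
#' @param labels binary 0/1 truth.
#' @param cluster_ids cluster (subject) identifier per record.
#' @param se_method `"components"` (default) or `"jackknife"`.
#' @return a `clustered_auc` list: `auc`, `se`, `n_clusters`, `n_pos`,
#'   `n_neg`, `se_defined` (FALSE with `se = NA` when fewer than 2 clusters).
#' @export
clustered_auc <- function(probabilities, labels, cluster_ids,
                          se_method = c("components", "jackknife")) {
  se_method <- match.arg(se_method)
  stopifnot(length(probabilities) == length(labels),
            length(labels) == length(cluster_ids))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  cluster_ids <- as.character(cluster_ids)
  A <- auc_mann_whitney(probabilities, labels)
  cls <- unique(cluster_ids)
  I <- length(cls)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (I < 2) {
    return(structure(list(auc = A, se = NA_real_, n_clusters = I,
                          n_pos = n1, n_neg = n0, se_defined = FALSE,
                          se_method = se_method),
                     class = "clustered_auc"))
  }
  se <- if (se_method == "components") {
    pos <- labels == 1
    neg <- labels == 0
    # placement values: each positive against the negative distribution
    v10 <- vapply(probabilities[pos], function(x) {
      mean((x > probabilities[neg]) + 0.5 * (x == probabilities[neg]))
    }, numeric(1))
    v01 <- vapply(probabilities[neg], function(x) {
      mean((probabilities[pos] > x) + 0.5 * (probabilities[pos] == x))
    }, numeric(1))
    X <- vapply(cls, function(cc) sum(v10[cluster_ids[pos] == cc]), numeric(1))
    Y <- vapply(cls, function(cc) sum(v01[cluster_ids[neg] == cc]), numeric(1))
    m1 <- vapply(cls, function(cc) sum(pos & cluster_ids == cc), numeric(1))
    m0 <- vapply(cls, function(cc) sum(neg & cluster_ids == cc), numeric(1))
    I1 <- sum(m1 > 0)
    I0 <- sum(m0 > 0)
    v <- I1 / (I1 - 1) * sum((X - m1 * A)^2) / n1^2 +
      I0 / (I0 - 1) * sum((Y - m0 * A)^2) / n0^2 +
      2 * I / (I - 1) * sum((X - m1 * A) * (Y - m0 * A)) / (n1 * n0)
    sqrt(max(v, 0))
  } else {
    drop <- vapply(cls, function(cc) {
      keep <- cluster_ids != cc
      if (length(unique(labels[keep])) < 2) return(NA_real_)
      auc_mann_whitney(probabilities[keep], labels[keep])
    }, numeric(1))
    if (anyNA(drop)) {
      NA_real_
    } else {
      pseudo <- I * A - (I - 1) * drop
      sqrt(sum((pseudo - mean(pseudo))^2) / (I * (I - 1)))
    }
  }
  structure(list(auc = A, se = se, n_clusters = I, n_pos = n1, n_neg = n0,
                 se_defined = !is.na(se), se_method = se_method),
            class = "clustered_auc")
}

#' @export
print.clustered_auc <- function(x, ...) {
  cat(sprintf("cROC AUC %.3f (SE %.3f; %d clusters, %d pos / %d neg)\n",
              x$auc, x$se, x$n_clusters, x$n_pos, x$n_neg))
  invisible(x)
}

#' Per-fold AUC percentage difference with combined Z-test
#'
#' Per fold: `100 * (AUC_model - AUC_ref) / AUC_ref` (mean of per-fold
#' ratios, the study's reporting convention — not the ratio of means). The
#' summary mean is taken over all R*K folds; the reported SE respects the
#' repetition structure (SE of the R repetition means), with the plain
#' across-fold SE also returned. Significance: a two-tailed Z-test of the
#' fold differences within each repetition, the R p-values combined by
#' Bonferroni (`min(1, R * min p)`).
#'
#' @param model_aucs,reference_aucs data frames with columns `repetition`,
#'   `fold`, `auc`, computed on matched splits.
#' @return a `diff_result`: `mean_diff_pct`, `se_diff_pct` (repetition
#'   structure), `se_folds_pct`, `z_p` (combined), `per_repetition_p`,
#'   `degenerate` (TRUE when some repetition had zero spread).
#' @export
auc_percentage_difference <- function(model_aucs, reference_aucs) {
  m <- merge(model_aucs, reference_aucs, by = c("repetition", "fold"),
             suffixes = c("_model", "_ref"))
  if (nrow(m) != nrow(model_aucs)) {
    stop("model and reference folds are not matched", call. = FALSE)
  }
  if (any(m$auc_ref == 0)) {
    stop("reference AUC is zero in some fold; percentage difference ",
         "undefined", call. = FALSE)
  }
  m$diff <- 100 * (m$auc_model - m$auc_ref) / m$auc_ref
  reps <- sort(unique(m$repetition))
  R <- length(reps)
  rep_means <- vapply(reps, function(r) mean(m$diff[m$repetition == r]),
                      numeric(1))
  per_rep_p <- vapply(reps, function(r) {
    d <- m$diff[m$repetition == r]
    se <- stats::sd(d) / sqrt(length(d))
    if (!is.finite(se) || se == 0) {
      return(if (mean(d) == 0) 1 else 0)
    }
    2 * stats::pnorm(-abs(mean(d) / se))
  }, numeric(1))
  se_reps <- if (R > 1) stats::sd(rep_means) / sqrt(R) else NA_real_
  structure(list(
    mean_diff_pct = mean(m$diff),
    se_diff_pct = se_reps,
    se_folds_pct = stats::sd(m$diff) / sqrt(nrow(m)),
    z_p = min(1, R * min(per_rep_p)),
    per_repetition_p = per_rep_p,
    degenerate = any(vapply(reps, function(r)
      stats::sd(m$diff[m$repetition == r]) == 0, logical(1)))
  ), class = "diff_result")
}

#' Combined 5x2-CV F-test for clustered matched-pair success probabilities
#'
#' A McNemar-style comparison of two classifiers' marginal probabilities of
#' success (success = predicted class equals the true label) over an R x 2
#' CV. Per split (repetition i, fold j) the difference d_i^(j) is estimated
#' cluster-robustly as the unweighted mean over test subjects of the
#' within-subject success-rate difference. With s_i^2 the within-repetition
#' variance of the two fold differences, F = sum_ij d_ij^2 / (2 sum_i s_i^2)
#' is referred to the F(2R, R) distribution ((10, 5) at R = 5).
#'
#' @param model_pred,reference_pred data frames of matched test predictions
#'   with columns `repetition`, `fold`, `row_id`, `subject_id`, `truth`,
#'   `pred_class` (as produced by [run_repeated_cv()]).
#' @param segment_weighted if TRUE, d is the segment-weighted success
#'   difference instead of the subject-mean (sensitivity variant).
#' @return an `f_test_result`: `f_statistic`, `df`, `p`, `degenerate`
#'   (all-zero differences; then p = 1), `d` (R x 2 matrix).
#' @export
combined_clustered_f_test <- function(model_pred, reference_pred,
                                      segment_weighted = FALSE) {
  key <- c("repetition", "fold", "row_id")
  m <- merge(model_pred[c(key, "subject_id", "truth", "pred_class")],
             reference_pred[c(key, "pred_class")],
             by = key, suffixes = c("_model", "_ref"))
  if (nrow(m) != nrow(model_pred)) {
    stop("model and reference predictions are not matched-pair ",
         "(fold membership differs)", call. = FALSE)
  }
  reps <- sort(unique(m$repetition))
  folds <- sort(unique(m$fold))
  if (length(folds) != 2) {
    stop("unsupported scheme: the combined F-test is defined for K = 2 only",
         call. = FALSE)
  }
  R <- length(reps)
  d <- matrix(NA_real_, R, 2)
  for (i in seq_len(R)) {
    for (j in 1:2) {
      sub <- m[m$repetition == reps[i] & m$fold == folds[j], ]
      succ_m <- sub$pred_class_model == sub$truth
      succ_r <- sub$pred_class_ref == sub$truth
      d[i, j] <- if (segment_weighted) {
        mean(succ_m) - mean(succ_r)
      } else {
        mean(tapply(succ_m - succ_r, sub$subject_id, mean))
      }
    }
  }
  if (all(d == 0)) {
    return(structure(list(f_statistic = 0, df = c(2 * R, R), p = 1,
                          degenerate = TRUE, d = d),
                     class = "f_test_result"))
  }
  s2 <- apply(d, 1, function(x) sum((x - mean(x))^2))
  denom <- 2 * sum(s2)
  f <- if (denom == 0) Inf else sum(d^2) / denom
  p <- if (is.infinite(f)) 0 else
    stats::pf(f, 2 * R, R, lower.tail = FALSE)
  structure(list(f_statistic = f, df = c(2 * R, R), p = p,
                 degenerate = FALSE, d = d),
            class = "f_test_result")
}

#' Cramer's V between two categorical/ordinal variables
#'
#' Classical bias-uncorrected formula `V = sqrt(chi2 / (n * (min(r, c) -
#' 1)))` on the observed contingency table (empty rows/columns dropped). A
#' constant variable yields 0 with a warning.
#'
#' @param x,y equal-length vectors.
#' @return V in [0, 1].
#' @export
cramers_v <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  tab <- table(x, y)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    warning("degenerate contingency table (a variable is constant); V = 0")
    return(0)
  }
  chi2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$statistic)
  unname(sqrt(chi2 / (sum(tab) * (min(dim(tab)) - 1))))
}

#' Bonferroni adjustment
#'
#' @param p_values p-values in [0, 1].
#' @param m number of comparisons (>= 1).
#' @return `pmin(1, p * m)`.
#' @export
bonferroni_adjust <- function(p_values, m) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  stopifnot(all(p_values >= 0 & p_values <= 1))
  pmin(1, p_values * m)
}
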