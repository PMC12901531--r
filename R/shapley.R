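#' @title Exact model-agnostic Shapley attribution and global aggregation
#' @description Attributions are computed on the probability scale by exact
#'   enumeration of the 2^m coalitions (feasible because models use at most
#'   a handful of score variables). The value of a coalition S is the mean
#'   predicted probability over the background records with the explained
#'   record's values substituted on S (interventional marginalization). The
#'   study's scalar explainability summary, the Global Absolute Shapley,
#'   aggregates absolute local mean attributions over score levels,
#'   variables, and CV folds.
#' @name shapley
NULL

# value of every coalition for a batch of instances: returns a matrix
# (n_instances x 2^m) of v(S); coalitions indexed by bitmask + 1
coalition_values <- function(model, background, instances) {
  vars <- model$spec$variables
  m <- length(vars)
  n_bg <- nrow(background)
  n_in <- nrow(instances)
  n_coal <- 2^m
  bg <- as.data.frame(background)
  masks <- lapply(0:(n_coal - 1), function(b) which(bitwAnd(b, 2^(0:(m - 1))) > 0))
  vals <- matrix(NA_real_, n_in, n_coal)
  # one prediction call per coalition over (instance x background) rows
  for (ci in seq_len(n_coal)) {
    on_vars <- vars[masks[[ci]]]
    big <- bg[rep(seq_len(n_bg), times = n_in), , drop = FALSE]
    if (length(on_vars) > 0) {
      cols <- variable_column(on_vars)
      inst_rep <- instances[rep(seq_len(n_in), each = n_bg), cols,
                            drop = FALSE]
      big[cols] <- inst_rep
    }
    p <- predict_probability(model, big)
    vals[, ci] <- colMeans(matrix(p, n_bg, n_in))
  }
  attr(vals, "masks") <- masks
  vals
}

shapley_from_values <- function(vals, m) {
  masks <- attr(vals, "masks")
  sizes <- vapply(masks, length, integer(1))
  w <- function(s) factorial(s) * factorial(m - s - 1) / factorial(m)
  phi <- matrix(0, nrow(vals), m)
  for (b in 0:(2^m - 1)) {
    ci <- b + 1
    for (j in seq_len(m)) {
      if (bitwAnd(b, 2^(j - 1)) == 0) {
        cj <- b + 2^(j - 1) + 1
        phi[, j] <- phi[, j] + w(sizes[ci]) * (vals[, cj] - vals[, ci])
      }
    }
  }
  phi
}

#' Exact Shapley attribution for one record
#'
#' Enumerates all coalitions of the model's variables; the coalition value is
#' the mean predicted probability over the background with the record's
#' values substituted on the coalition. Efficiency holds: attributions sum to
#' `v(all variables) - v(empty set)`.
#'
#' @param model a [train_model()] result with at most 4 variables.
#' @param background a [cohort] (or data frame) of background records —
#'   conventionally the split's original, un-oversampled training records.
#' @param instance a single-row cohort/data frame to explain.
#' @return named numeric vector of per-variable attributions.
#' @export
exact_shapley_values <- function(model, background, instance) {
  stopifnot(inherits(model, "trained_model"))
  vars <- model$spec$variables
  if (length(vars) > 4) {
    stop("exact enumeration supports at most 4 variables", call. = FALSE)
  }
  if (nrow(background) == 0) stop("empty background", call. = FALSE)
  stopifnot(nrow(instance) == 1)
  vals <- coalition_values(model, background, as.data.frame(instance))
  phi <- shapley_from_values(vals, length(vars))[1, ]
  names(phi) <- vars
  phi
}

# per-record attribution matrix for a whole fold (vectorized over records)
fold_shapley_attributions <- function(model, background, instances,
                                      max_background = 200, seed = 1L) {
  bg <- as.data.frame(background)
  if (nrow(bg) > max_background) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    bg <- bg[sample(nrow(bg), max_background), , drop = FALSE]
  }
  vals <- coalition_values(model, bg, as.data.frame(instances))
  phi <- shapley_from_values(vals, length(model$spec$variables))
  colnames(phi) <- model$spec$variables
  phi
}

#' Local mean Shapley table for one fold
#'
#' Averages attributions per variable and score level: cell (variable, s) is
#' the mean attribution over the fold's records whose variable equals s.
#' Score levels with no supporting record are absent from the table, not
#' zero.
#'
#' @param attributions matrix of per-record attributions (records x
#'   variables, as from [exact_shapley_values()] stacked row-wise).
#' @param records the records the attributions belong to (for their score
#'   values).
#' @return data frame with columns `variable`, `score`, `value`, `support`.
#' @export
local_mean_shapley <- function(attributions, records) {
  attributions <- as.matrix(attributions)
  vars <- colnames(attributions)
  stopifnot(!is.null(vars), nrow(attributions) == nrow(records))
  rec <- as.data.frame(records)
  out <- list()
  for (v in vars) {
    s <- rec[[variable_column(v)]]
    for (lev in sort(unique(s))) {
      sel <- s == lev
      out[[length(out) + 1]] <- data.frame(
        variable = v, score = lev,
        value = mean(attributions[sel, v]),
        support = sum(sel), stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Global Absolute Shapley over CV folds
#'
#' Per fold: the arithmetic mean of the absolute local mean Shapley values
#' over the populated (variable, score) cells (optionally weighted by cell
#' support). Globally: mean and SE over the R*K folds.
#'
#' @param shapley_table data frame with columns `repetition`, `fold`,
#'   `variable`, `score`, `value`, `support` (stacked [local_mean_shapley()]
#'   tables).
#' @param support_weighted weight cells by their record support instead of
#'   equally (default FALSE).
#' @return a `global_shapley` list: `mean`, `se`, `per_fold` (data frame
#'   `repetition`, `fold`, `value`).
#' @export
global_absolute_shapley <- function(shapley_table, support_weighted = FALSE) {
  stopifnot(nrow(shapley_table) > 0)
  key <- interaction(shapley_table$repetition, shapley_table$fold,
                     drop = TRUE)
  per <- lapply(split(shapley_table, key), function(tb) {
    v <- if (support_weighted) {
      sum(abs(tb$value) * tb$support) / sum(tb$support)
    } else {
      mean(abs(tb$value))
    }
    data.frame(repetition = tb$repetition[1], fold = tb$fold[1], value = v)
  })
  per <- do.call(rbind, per)
  per <- per[order(per$repetition, per$fold), ]
  rownames(per) <- NULL
  structure(list(
    mean = mean(per$value),
    se = if (nrow(per) > 1) stats::sd(per$value) / sqrt(nrow(per)) else 0,
    per_fold = per
  ), class = "global_shapley")
}

#' Percentage difference in Global Absolute Shapley with corrected paired t
#'
#' Per-fold percentage differences relative to the reference, tested with
#' the variance-corrected resampled-CV paired t-test: the naive variance of
#' the fold differences is multiplied by `(1/(R*K) + n_test/n_train)` (the
#' ratio is `1/(K-1)`, i.e. 1 for K = 2), with `R*K - 1` degrees of freedom.
#'
#' @param model_per_fold,reference_per_fold data frames `repetition`,
#'   `fold`, `value` on matched splits (as in
#'   [global_absolute_shapley()]`$per_fold`).
#' @param test_train_ratio `n_test/n_train`; defaults to `1/(K-1)` inferred
#'   from the fold count.
#' @return a `diff_result` with `mean_diff_pct`, `se_diff_pct`, `t_p`,
#'   `t_statistic`, `df`, `degenerate`.
#' @export
shapley_percentage_difference <- function(model_per_fold, reference_per_fold,
                                          test_train_ratio = NULL) {
  m <- merge(model_per_fold, reference_per_fold,
             by = c("repetition", "fold"), suffixes = c("_model", "_ref"))
  if (nrow(m) != nrow(model_per_fold)) {
    stop("model and reference folds are not matched", call. = FALSE)
  }
  if (any(m$value_ref == 0)) {
    stop("reference Global Absolute Shapley is zero in some fold",
         call. = FALSE)
  }
  K <- length(unique(m$fold))
  if (is.null(test_train_ratio)) test_train_ratio <- 1 / (K - 1)
  d <- 100 * (m$value_model - m$value_ref) / m$value_ref
  n <- length(d)
  var_naive <- stats::var(d)
  if (!is.finite(var_naive) || var_naive == 0) {
    return(structure(list(mean_diff_pct = mean(d), se_diff_pct = 0,
                          t_statistic = NA_real_, df = n - 1,
                          t_p = if (mean(d) == 0) 1 else 0,
                          degenerate = TRUE), class = "diff_result"))
  }
  se_corr <- sqrt((1 / n + test_train_ratio) * var_naive)
  t_stat <- mean(d) / se_corr
  structure(list(
    mean_diff_pct = mean(d),
    se_diff_pct = se_corr,
    t_statistic = t_stat,
    df = n - 1,
    t_p = 2 * stats::pt(-abs(t_stat), df = n - 1),
    degenerate = FALSE
  ), class = "diff_result")
}
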