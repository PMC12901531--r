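#' @title Full model-comparison study
#' @description Orchestrates the evaluation: every {algorithm} x {variable
#'   set} model plus the two simulation sanity variables is run on shared
#'   grouped-stratified CV splits and compared against the reference model
#'   (logistic regression on LGE + FDG) through five significance criteria,
#'   generalization gaps and an optional sample-size sweep.
#' @name comparison-pipeline
NULL

DEFAULT_VARIABLE_SETS <- list(
  c("fdg"), c("lge"), c("wma"),
  c("fdg", "lge"), c("lge", "wma"), c("fdg", "lge", "wma")
)

build_study_specs <- function(reference, algorithms, variable_sets,
                              include_simulations, seed) {
  specs <- list()
  add <- function(sp) {
    id <- format(sp)
    if (is.null(specs[[id]])) specs[[id]] <<- sp
  }
  add(reference)
  for (alg in algorithms) {
    for (vs in variable_sets) add(model_spec(alg, vs, seed = seed))
    if (include_simulations) {
      add(model_spec(alg, "sim_perfect", seed = seed))
      add(model_spec(alg, "sim_flawed", seed = seed))
    }
  }
  specs
}

#' Evaluate the five significance criteria for one comparison row
#'
#' Criteria: (1) mean Diff cROC AUC > 10%; (2) Bonferroni-adjusted Z-test
#' p < .05; (3) Bonferroni-adjusted combined F-test p < .05; (4) mean Diff
#' Global Absolute Shapley > 20%; (5) Bonferroni-adjusted corrected paired
#' t-test p < .05. Missing statistics evaluate to FALSE.
#'
#' @param row a single comparison row (list or one-row data frame) with
#'   `diff_auc_pct`, `z_p`, `ftest_p`, `diff_shapley_pct`, `t_p`.
#' @param m number of non-reference model comparisons for the Bonferroni
#'   adjustment.
#' @return named logical vector of the five flags.
#' @export
evaluate_significance_criteria <- function(row, m) {
  adj <- function(p) {
    if (is.null(p) || is.na(p)) NA_real_ else bonferroni_adjust(p, m)
  }
  val <- function(x) if (is.null(x) || is.na(x)) -Inf else x
  c(
    crit_diff_auc_gt_10 = val(row$diff_auc_pct) > 10,
    crit_diff_auc_p = isTRUE(adj(row$z_p) < 0.05),
    crit_ftest_p = isTRUE(adj(row$ftest_p) < 0.05),
    crit_diff_shapley_gt_20 = val(row$diff_shapley_pct) > 20,
    crit_diff_shapley_p = isTRUE(adj(row$t_p) < 0.05)
  )
}

#' Run the full comparison study on one cohort
#'
#' Trains and evaluates all requested models on shared splits and returns
#' one comparison row per model (the reference included, with zero
#' differences). The Bonferroni multiplicity `m` is the number of
#' non-reference models. Model failures yield a flagged row, not an abort.
#'
#' @param cohort a validated, filtered [cohort] (with simulation columns if
#'   `include_simulations`).
#' @param scheme a [cv_scheme()]; the combined F-test is reported only for
#'   K = 2.
#' @param reference reference [model_spec()] (default LogReg on LGE + FDG).
#' @param algorithms algorithm names to cross with the variable sets.
#' @param variable_sets list of character vectors (default: the six
#'   imaging-variable sets).
#' @param include_simulations evaluate each algorithm on the perfect/flawed
#'   simulation variables too.
#' @param compute_shapley compute the Shapley explainability track (exact
#'   attributions; slower).
#' @param shapley_max_background background cap per split.
#' @return a `comparison` data frame (one row per model) with the CV result
#'   in `attr(, "cv_result")` and `m` in `attr(, "bonferroni_m")`.
#' @export
run_full_comparison <- function(cohort,
                                scheme = cv_scheme(),
                                reference = model_spec("LogReg", c("fdg", "lge")),
                                algorithms = ALGORITHMS,
                                variable_sets = DEFAULT_VARIABLE_SETS,
                                include_simulations = TRUE,
                                compute_shapley = TRUE,
                                shapley_max_background = 200) {
  stopifnot(inherits(cohort, "cohort"))
  specs <- build_study_specs(reference, algorithms, variable_sets,
                             include_simulations, seed = scheme$base_seed)
  ref_id <- format(reference)
  cv <- run_repeated_cv(cohort, specs, scheme,
                        compute_shapley = compute_shapley,
                        shapley_max_background = shapley_max_background)
  rows <- compare_against_reference(cv, ref_id, specs)
  attr(rows, "cv_result") <- cv
  rows
}

compare_against_reference <- function(cv, ref_id, specs) {
  ids <- cv$model_ids
  if (!ref_id %in% ids) stop("reference model missing from the run",
                             call. = FALSE)
  m_bonf <- length(ids) - 1
  K <- cv$scheme$folds
  failed_ids <- unique(vapply(cv$failures, `[[`, character(1), "model"))

  ref_auc <- fold_clustered_aucs(cv, ref_id, "test")
  ref_pred <- cv$predictions[cv$predictions$model == ref_id &
                               cv$predictions$role == "test", ]
  ref_shap_fold <- NULL
  if (!is.null(cv$shapley)) {
    ref_shap_fold <- global_absolute_shapley(
      cv$shapley[cv$shapley$model == ref_id, ])$per_fold
  }

  rows <- lapply(ids, function(id) {
    spec <- specs[[id]]
    base <- data.frame(
      model = id, algorithm = spec$algorithm,
      variables = paste(spec$variables, collapse = "+"),
      is_reference = id == ref_id, failed = id %in% failed_ids,
      auc_mean = NA_real_, auc_se = NA_real_,
      train_auc = NA_real_, gap_pct = NA_real_,
      diff_auc_pct = NA_real_, diff_auc_se = NA_real_, z_p = NA_real_,
      ftest_f = NA_real_, ftest_p = NA_real_,
      shapley_mean = NA_real_, shapley_se = NA_real_,
      diff_shapley_pct = NA_real_, diff_shapley_se = NA_real_,
      t_p = NA_real_,
      stringsAsFactors = FALSE
    )
    if (base$failed) return(base)
    auc_t <- fold_clustered_aucs(cv, id, "test")
    auc_tr <- fold_clustered_aucs(cv, id, "train")
    base$auc_mean <- mean(auc_t$auc)
    base$auc_se <- stats::sd(auc_t$auc) / sqrt(nrow(auc_t))
    base$train_auc <- mean(auc_tr$auc)
    if (any(auc_tr$auc == 0)) {
      stop("training AUC of 0 for model '", id, "'", call. = FALSE)
    }
    gaps <- 100 * (auc_tr$auc - auc_t$auc) / auc_tr$auc
    base$gap_pct <- mean(gaps)
    if (id != ref_id) {
      # undefined contrasts (e.g. a zero reference AUC in a degenerate tiny
      # fold) leave NA statistics instead of aborting the study
      dd <- tryCatch(auc_percentage_difference(auc_t, ref_auc),
                     error = function(e) NULL)
      if (!is.null(dd)) {
        base$diff_auc_pct <- dd$mean_diff_pct
        base$diff_auc_se <- dd$se_folds_pct
        base$z_p <- dd$z_p
      }
      if (K == 2) {
        pred <- cv$predictions[cv$predictions$model == id &
                                 cv$predictions$role == "test", ]
        ft <- combined_clustered_f_test(pred, ref_pred)
        base$ftest_f <- ft$f_statistic
        base$ftest_p <- ft$p
      }
    } else {
      base$diff_auc_pct <- 0
      base$diff_auc_se <- 0
    }
    if (!is.null(cv$shapley)) {
      gs <- global_absolute_shapley(cv$shapley[cv$shapley$model == id, ])
      base$shapley_mean <- gs$mean
      base$shapley_se <- gs$se
      if (id != ref_id) {
        sd_ <- tryCatch(
          shapley_percentage_difference(gs$per_fold, ref_shap_fold),
          error = function(e) NULL)
        if (!is.null(sd_)) {
          base$diff_shapley_pct <- sd_$mean_diff_pct
          base$diff_shapley_se <- sd_$se_diff_pct
          base$t_p <- sd_$t_p
        }
      } else {
        base$diff_shapley_pct <- 0
        base$diff_shapley_se <- 0
      }
    }
    base
  })
  out <- do.call(rbind, rows)
  flags <- t(vapply(seq_len(nrow(out)), function(i) {
    if (out$is_reference[i] || out$failed[i]) {
      stats::setNames(rep(FALSE, 5),
                      names(evaluate_significance_criteria(out[1, ], 1)))
    } else {
      evaluate_significance_criteria(out[i, ], m_bonf)
    }
  }, logical(5)))
  out <- cbind(out, as.data.frame(flags))
  attr(out, "bonferroni_m") <- m_bonf
  class(out) <- c("comparison", "data.frame")
  out
}

#' Training/testing generalization gap per model
#'
#' Per fold, `gap = 100 * (AUC_train - AUC_test) / AUC_train`, averaged over
#' folds; gaps above 20% flag overfitting.
#'
#' @param cv_result a [run_repeated_cv()] result.
#' @return data frame `model`, `gap_pct`, `overfit` (gap > 20%).
#' @export
performance_gap_analysis <- function(cv_result) {
  ids <- setdiff(cv_result$model_ids,
                 vapply(cv_result$failures, `[[`, character(1), "model"))
  rows <- lapply(ids, function(id) {
    tr <- fold_clustered_aucs(cv_result, id, "train")
    te <- fold_clustered_aucs(cv_result, id, "test")
    if (any(tr$auc == 0)) stop("training AUC of 0 for '", id, "'",
                               call. = FALSE)
    g <- mean(100 * (tr$auc - te$auc) / tr$auc)
    data.frame(model = id, gap_pct = g, overfit = g > 20,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Sample-size sweep over CV schemes
#'
#' Re-runs the comparison under each scheme (default 5x2, 5x3, 5x5, 5x10,
#' i.e. 50/66.6/80/90% of the data used in training). The combined F-test
#' is defined only for K = 2 and reported as NA otherwise.
#'
#' @param cohort a validated, filtered [cohort].
#' @param schemes list of [cv_scheme()]s.
#' @param ... passed to [run_full_comparison()].
#' @return named list of `comparison` data frames, each with a
#'   `training_fraction_pct` column.
#' @export
sample_size_sweep <- function(cohort,
                              schemes = lapply(c(2, 3, 5, 10), function(k)
                                cv_scheme(5, k)),
                              ...) {
  out <- list()
  for (sch in schemes) {
    rows <- run_full_comparison(cohort, scheme = sch, ...)
    # truncated to one decimal: 50, 66.6, 80, 90 for K = 2, 3, 5, 10
    rows$training_fraction_pct <- floor(1000 * (sch$folds - 1) / sch$folds) / 10
    out[[format(sch)]] <- rows
  }
  out
}

#' Write a study report
#'
#' Emits `comparison.csv` (all rows) and `summary.json` (package version,
#' scheme, Bonferroni m, failure log). Deterministic for a fixed study.
#'
#' @param rows a `comparison` data frame from [run_full_comparison()].
#' @param output_dir directory (created if missing).
#' @return invisible vector of the written paths.
#' @export
write_report <- function(rows, output_dir) {
  stopifnot(nrow(rows) > 0)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(output_dir, "comparison.csv")
  utils::write.csv(as.data.frame(rows), csv, row.names = FALSE)
  cv <- attr(rows, "cv_result")
  summary <- list(
    package = "segrecov",
    version = as.character(utils::packageVersion("segrecov")),
    n_models = nrow(rows),
    bonferroni_m = attr(rows, "bonferroni_m"),
    scheme = if (!is.null(cv)) format(cv$scheme) else NA,
    base_seed = if (!is.null(cv)) cv$scheme$base_seed else NA,
    failures = if (!is.null(cv)) cv$failures else list()
  )
  js <- file.path(output_dir, "summary.json")
  jsonlite::write_json(summary, js, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(csv, js))
}
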