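#' @title Repeated grouped-stratified cross-validation
#' @description Partitioning keeps every segment of a subject in one fold
#'   (grouping, to prevent subject-level leakage) while steering each fold
#'   toward the cohort's recovered-segment share (stratification), repeated R
#'   times with independent re-splits. Minority oversampling (random
#'   replication with replacement) is applied to training folds only.
#' @name cv-engine
NULL

#' Cross-validation scheme
#'
#' @param repetitions number of independent re-splits R (default 5).
#' @param folds folds K per repetition (default 2; the combined F-test is
#'   defined only for K = 2).
#' @param base_seed integer; repetition r uses seed `base_seed + r`.
#' @return a `cv_scheme`.
#' @export
cv_scheme <- function(repetitions = 5, folds = 2, base_seed = 1L) {
  stopifnot(repetitions >= 1, folds >= 2)
  structure(list(repetitions = as.integer(repetitions),
                 folds = as.integer(folds),
                 base_seed = as.integer(base_seed)),
            class = "cv_scheme")
}

#' @export
format.cv_scheme <- function(x, ...) paste0(x$repetitions, "x", x$folds)

#' Build a grouped, class-stratified fold plan
#'
#' Greedy assignment per repetition: subjects are sorted by descending count
#' of recovered segments (ties shuffled under the repetition seed) and each
#' is placed into the fold currently furthest below its target share of
#' recovered segments, with fold size as tie-break. Subjects without any
#' recovered segment (for whom the positive-deficit rule is vacuous) are
#' steered first to folds still lacking unrecovered segments — without this,
#' a fold holding a fully-recovered subject could never become two-class at
#' large K. Over a fixed number of
#' seeded draws, the plan whose worst fold deviates least from the cohort's
#' recovered-segment fraction is kept; draws leaving a single-class fold are
#' discarded (an error if none survives).
#'
#' @param cohort a validated [cohort].
#' @param scheme a [cv_scheme()].
#' @return a `fold_plan`: per repetition, a named integer vector mapping
#'   subject id to fold index.
#' @export
make_group_stratified_folds <- function(cohort, scheme) {
  stopifnot(inherits(cohort, "cohort"), inherits(scheme, "cv_scheme"))
  K <- scheme$folds
  subj <- unique(cohort$subject_id)
  if (K > length(subj)) {
    stop("unsupported scheme: K = ", K, " exceeds the ", length(subj),
         " subjects", call. = FALSE)
  }
  pos <- tapply(cohort$recovery, cohort$subject_id, sum)[subj]
  tot <- tapply(rep(1, nrow(cohort)), cohort$subject_id, sum)[subj]
  target_pos <- sum(pos) / K

  plan <- vector("list", scheme$repetitions)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  cohort_frac <- mean(cohort$recovery)
  for (r in seq_len(scheme$repetitions)) {
    assigned <- NULL
    best_dev <- Inf
    for (retry in 0:59) {
      set.seed(scheme$base_seed + r + retry * 10007L)
      ord <- order(-pos, stats::runif(length(subj)))
      fold_pos <- numeric(K)
      fold_neg <- numeric(K)
      fold_n <- numeric(K)
      a <- integer(length(subj))
      names(a) <- subj
      for (s in ord) {
        if (pos[s] == 0 && any(fold_n > 0 & fold_neg == 0)) {
          cand <- which(fold_n > 0 & fold_neg == 0)
        } else {
          deficit <- target_pos - fold_pos
          cand <- which(deficit == max(deficit))
        }
        if (length(cand) > 1) cand <- cand[fold_n[cand] == min(fold_n[cand])]
        f <- if (length(cand) > 1) sample(cand, 1) else cand
        a[subj[s]] <- f
        fold_pos[f] <- fold_pos[f] + pos[s]
        fold_neg[f] <- fold_neg[f] + tot[s] - pos[s]
        fold_n[f] <- fold_n[f] + tot[s]
      }
      fracs <- vapply(seq_len(K), function(f) {
        rec <- cohort$recovery[cohort$subject_id %in% subj[a[subj] == f]]
        if (length(rec) == 0 || length(unique(rec)) < 2) NA_real_
        else mean(rec)
      }, numeric(1))
      if (anyNA(fracs)) next           # a single-class fold: discard draw
      dev <- max(abs(fracs - cohort_frac))
      if (dev < best_dev) {
        best_dev <- dev
        assigned <- a
      }
      if (dev <= 0.05) break           # already tightly stratified
    }
    if (is.null(assigned)) {
      stop("could not build a fold plan with both classes in every fold ",
           "(repetition ", r, ")", call. = FALSE)
    }
    plan[[r]] <- assigned
  }
  structure(plan, class = "fold_plan", scheme = scheme)
}

#' Oversample the minority class by random replication
#'
#' Minority-class records are drawn with replacement until both classes have
#' equal counts; every original record is retained. Applied to training
#' folds only — test folds are never resampled.
#'
#' @param records training records (a [cohort] or data frame with
#'   `recovery`).
#' @param seed integer seed for the replicate draw.
#' @return the augmented records (original rows first, replicates appended).
#' @export
oversample_minority <- function(records, seed = 1L) {
  counts <- table(factor(records$recovery, levels = c(0, 1)))
  if (any(counts == 0)) stop("oversampling needs both classes", call. = FALSE)
  minority <- as.integer(names(counts)[which.min(counts)])
  deficit <- abs(diff(as.integer(counts)))
  if (deficit == 0) return(records)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  idx <- which(records$recovery == minority)
  extra <- sample(idx, deficit, replace = TRUE)
  out <- rbind(as.data.frame(records), as.data.frame(records)[extra, ])
  rownames(out) <- NULL
  out
}

split_seed <- function(base_seed, repetition, fold) {
  ((abs(as.numeric(base_seed)) %% 100003) * 10007 +
     repetition * 101 + fold) %% .Machine$integer.max
}

#' Run repeated grouped-stratified CV for a set of models
#'
#' For each repetition and fold, every model spec is trained on the
#' oversampled complement of the held-out fold and applied to (a) the
#' held-out fold and (b) the original, un-oversampled training records (for
#' generalization-gap analysis). All models share identical splits — the
#' matched-pair design underlying the comparison statistics. Subject-level
#' leakage is asserted on every split.
#'
#' @param cohort a validated, filtered [cohort].
#' @param specs a named list of [model_spec()]s (names become model ids;
#'   unnamed lists are labelled by `format()`).
#' @param scheme a [cv_scheme()].
#' @param compute_shapley also compute exact Shapley attributions for every
#'   test record (background: the split's original training records) and
#'   stack the per-fold local mean Shapley tables into `$shapley`.
#' @param shapley_max_background cap on background records (seeded
#'   subsample beyond it).
#' @return a `cv_result`: list with `predictions` (one row per record x
#'   repetition x fold x model x role), `fold_plan`, `scheme` and (when
#'   requested) `shapley`. Training failures are recorded in `$failures`
#'   rather than aborting the run.
#' @export
run_repeated_cv <- function(cohort, specs, scheme = cv_scheme(),
                            compute_shapley = FALSE,
                            shapley_max_background = 200) {
  stopifnot(inherits(cohort, "cohort"), length(specs) >= 1)
  if (inherits(specs, "model_spec")) specs <- list(specs)
  ids <- names(specs)
  if (is.null(ids) || any(ids == "")) {
    ids <- vapply(specs, format, character(1))
    names(specs) <- ids
  }
  plan <- make_group_stratified_folds(cohort, scheme)
  df <- as.data.frame(cohort)
  df$.row <- seq_len(nrow(df))
  out <- list()
  shap <- list()
  failures <- list()

  for (r in seq_len(scheme$repetitions)) {
    assign_map <- plan[[r]]
    for (j in seq_len(scheme$folds)) {
      test_subj <- names(assign_map)[assign_map == j]
      test <- df[df$subject_id %in% test_subj, ]
      train <- df[!df$subject_id %in% test_subj, ]
      if (length(intersect(unique(train$subject_id),
                           unique(test$subject_id))) > 0) {
        stop("internal leakage check failed", call. = FALSE)  # nocov
      }
      # oversampled training data carries intentional duplicates, so it is
      # handled as plain records, not re-validated as a cohort
      aug <- oversample_minority(train, seed = split_seed(scheme$base_seed, r, j))
      for (id in ids) {
        spec <- specs[[id]]
        split_spec <- spec
        split_spec$seed <- as.integer(split_seed(spec$seed, r, j))
        fit <- tryCatch(
          train_model(split_spec, aug, n_before = nrow(train)),
          error = function(e) e
        )
        if (inherits(fit, "error")) {
          failures[[length(failures) + 1]] <- list(
            repetition = r, fold = j, model = id,
            message = conditionMessage(fit)
          )
          next
        }
        for (role in c("test", "train")) {
          part <- if (role == "test") test else train
          prob <- predict_probability(fit, part)
          out[[length(out) + 1]] <- data.frame(
            repetition = r, fold = j, model = id, role = role,
            row_id = part$.row, subject_id = part$subject_id,
            truth = part$recovery, prob = prob,
            pred_class = as.integer(prob >= 0.5),
            stringsAsFactors = FALSE
          )
        }
        if (compute_shapley) {
          phi <- fold_shapley_attributions(
            fit, train, test, max_background = shapley_max_background,
            seed = split_seed(scheme$base_seed + 7L, r, j)
          )
          lm_tab <- local_mean_shapley(phi, test)
          lm_tab$repetition <- r
          lm_tab$fold <- j
          lm_tab$model <- id
          shap[[length(shap) + 1]] <- lm_tab
        }
      }
    }
  }
  structure(list(predictions = do.call(rbind, out), fold_plan = plan,
                 scheme = scheme, model_ids = ids, n_records = nrow(df),
                 shapley = if (compute_shapley) do.call(rbind, shap),
                 failures = failures),
            class = "cv_result")
}

#' Per-split clustered AUC table for one model
#'
#' @param cv_result a [run_repeated_cv()] result.
#' @param model model id.
#' @param role `"test"` (default) or `"train"`.
#' @return data frame `repetition`, `fold`, `auc`, `se`.
#' @export
fold_clustered_aucs <- function(cv_result, model, role = "test") {
  pr <- cv_result$predictions
  pr <- pr[pr$model == model & pr$role == role, ]
  if (nrow(pr) == 0) stop("no predictions for model '", model, "'",
                          call. = FALSE)
  key <- unique(pr[c("repetition", "fold")])
  key <- key[order(key$repetition, key$fold), ]
  res <- lapply(seq_len(nrow(key)), function(i) {
    sub <- pr[pr$repetition == key$repetition[i] & pr$fold == key$fold[i], ]
    ca <- clustered_auc(sub$prob, sub$truth, sub$subject_id)
    data.frame(repetition = key$repetition[i], fold = key$fold[i],
               auc = ca$auc, se = ca$se)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
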