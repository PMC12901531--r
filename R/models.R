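#' @title Classifier families over ordinal viability scores
#' @description Seven algorithm families are trained over any subset of the
#'   predictor variables under one probability-output contract: logistic
#'   regression (LogReg), mixed-effects logistic regression with a per-subject
#'   random intercept (MELogReg), decision tree (DecTree), k-nearest
#'   neighbours (KNN), Gaussian Naive Bayes (NBayes), random forest (RF) and
#'   a radial-kernel support vector machine with Platt-scaled probabilities
#'   (SVM). Ordinal scores enter as numeric integers 0-4. Hyperparameters are
#'   fixed at documented defaults; no tuning is performed.
#' @name model-zoo
NULL

ALGORITHMS <- c("LogReg", "MELogReg", "DecTree", "KNN", "NBayes", "RF", "SVM")
MODEL_VARIABLES <- c("fdg", "lge", "wma", "sim_perfect", "sim_flawed")
SIM_VARIABLES <- c("sim_perfect", "sim_flawed")

# model variable name -> cohort column
variable_column <- function(v) ifelse(v == "wma", "wma_baseline", v)

#' Define a model: an {algorithm} x {variable set} pair
#'
#' @param algorithm one of `LogReg, MELogReg, DecTree, KNN, NBayes, RF, SVM`.
#' @param variables non-empty subset of `fdg, lge, wma, sim_perfect,
#'   sim_flawed`; the simulation variables are standalone sanity models and
#'   may not be mixed with imaging variables.
#' @param hyperparameters optional overrides of the documented defaults
#'   (`knn_k = 5`, `rf_ntree = 500`, `svm_cost = 1`, `tree` unlimited depth
#'   with minimum leaf 1, `nb_sd_floor = 1e-3`).
#' @param seed integer seed for the stochastic algorithms (RF, SVM
#'   probability calibration, DecTree/KNN tie handling).
#' @return a `model_spec`.
#' @export
model_spec <- function(algorithm, variables, hyperparameters = list(),
                       seed = 1L) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  stopifnot(length(variables) >= 1)
  bad <- setdiff(variables, MODEL_VARIABLES)
  if (length(bad) > 0) stop("unknown variable(s): ",
                            paste(bad, collapse = ", "), call. = FALSE)
  if (any(variables %in% SIM_VARIABLES) && length(variables) > 1) {
    stop("simulation variables are standalone; do not mix with imaging ",
         "variables", call. = FALSE)
  }
  hp <- utils::modifyList(
    list(knn_k = 5L, rf_ntree = 500L, svm_cost = 1, nb_sd_floor = 1e-3),
    hyperparameters
  )
  structure(list(algorithm = algorithm,
                 variables = sort(unique(variables)),
                 hyperparameters = hp, seed = as.integer(seed)),
            class = "model_spec")
}

#' @export
format.model_spec <- function(x, ...) {
  paste0(x$algorithm, "-", paste(toupper(x$variables), collapse = "+"))
}
#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", format(x), "\n")
  invisible(x)
}

model_frame <- function(spec, cohort, require_outcome = TRUE) {
  cols <- variable_column(spec$variables)
  missing <- setdiff(cols, names(cohort))
  if (length(missing) > 0) {
    stop("cohort lacks variable column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  X <- as.data.frame(lapply(as.data.frame(cohort)[cols], as.numeric))
  names(X) <- spec$variables
  if (require_outcome) {
    X$.y <- factor(cohort$recovery, levels = c(0, 1))
    X$.subject <- cohort$subject_id
  }
  X
}

#' Train a model on a (typically oversampled) training cohort
#'
#' @param spec a [model_spec()].
#' @param training a [cohort] containing both recovery classes.
#' @param n_before optional record count before oversampling, kept as
#'   training metadata.
#' @return a `trained_model` honouring the probability-output contract.
#' @export
train_model <- function(spec, training, n_before = nrow(training)) {
  stopifnot(inherits(spec, "model_spec"))
  if (length(unique(training$recovery)) < 2) {
    stop("training set is single-class", call. = FALSE)
  }
  df <- model_frame(spec, training)
  vars <- spec$variables
  hp <- spec$hyperparameters
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  fit <- switch(
    spec$algorithm,
    LogReg = {
      fo <- stats::as.formula(paste(".y ~", paste(vars, collapse = " + ")))
      suppressWarnings(stats::glm(fo, data = df, family = stats::binomial()))
    },
    MELogReg = {
      if (length(unique(df$.subject)) < 2) {
        stop("MELogReg needs at least 2 subjects", call. = FALSE)
      }
      fo <- stats::as.formula(paste(".y ~", paste(vars, collapse = " + "),
                                    "+ (1 | .subject)"))
      m <- tryCatch(
        suppressMessages(suppressWarnings(
          lme4::glmer(fo, data = df, family = stats::binomial(), nAGQ = 1L)
        )),
        error = function(e) stop("MELogReg failed to converge: ",
                                 conditionMessage(e), call. = FALSE)
      )
      m
    },
    DecTree = rpart::rpart(
      stats::as.formula(paste(".y ~", paste(vars, collapse = " + "))),
      data = df, method = "class",
      control = rpart::rpart.control(minsplit = 2, minbucket = 1, cp = 0,
                                     maxdepth = 30, xval = 0)
    ),
    KNN = list(train = as.matrix(df[vars]), cl = df$.y, k = hp$knn_k),
    NBayes = {
      m <- e1071::naiveBayes(df[vars], df$.y)
      # floor the class-conditional SDs: a within-class constant feature
      # (e.g. the perfect-case variable) otherwise yields degenerate
      # zero-variance Gaussians
      m$tables <- lapply(m$tables, function(tb) {
        tb[, 2] <- pmax(tb[, 2], hp$nb_sd_floor)
        tb
      })
      m
    },
    RF = randomForest::randomForest(df[vars], df$.y, ntree = hp$rf_ntree),
    SVM = e1071::svm(df[vars], df$.y, kernel = "radial", cost = hp$svm_cost,
                     probability = TRUE)
  )
  structure(list(spec = spec, fit = fit,
                 n_before = n_before, n_after = nrow(training)),
            class = "trained_model")
}

#' Predict the probability of recovery (class 1)
#'
#' Output is aligned with the input rows and bounded in [0, 1]. MELogReg
#' predictions for subjects unseen in training use the fixed effects only
#' (random intercept at its zero mean); training subjects get their
#' conditional random intercepts.
#'
#' @param model a [train_model()] result.
#' @param segments a [cohort] (or data frame) carrying the model's variables.
#' @return numeric vector of probabilities.
#' @export
predict_probability <- function(model, segments) {
  stopifnot(inherits(model, "trained_model"))
  spec <- model$spec
  df <- model_frame(spec, segments, require_outcome = FALSE)
  df$.subject <- as.character(segments$subject_id)
  vars <- spec$variables
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed + 1L)

  p <- switch(
    spec$algorithm,
    LogReg = suppressWarnings(
      unname(stats::predict(model$fit, newdata = df, type = "response"))
    ),
    MELogReg = unname(stats::predict(model$fit, newdata = df,
                                     type = "response",
                                     allow.new.levels = TRUE)),
    DecTree = unname(stats::predict(model$fit, newdata = df)[, "1"]),
    KNN = {
      k <- min(model$fit$k, nrow(model$fit$train))
      pred <- class::knn(model$fit$train, as.matrix(df[vars]),
                         model$fit$cl, k = k, prob = TRUE, use.all = TRUE)
      win <- attr(pred, "prob")
      ifelse(pred == "1", win, 1 - win)
    },
    NBayes = unname(stats::predict(model$fit, df[vars], type = "raw")[, "1"]),
    RF = unname(stats::predict(model$fit, df[vars], type = "prob")[, "1"]),
    SVM = {
      pr <- stats::predict(model$fit, df[vars], probability = TRUE)
      unname(attr(pr, "probabilities")[, "1"])
    }
  )
  p <- as.numeric(p)
  stopifnot(length(p) == nrow(df), all(p >= -1e-12), all(p <= 1 + 1e-12))
  pmin(pmax(p, 0), 1)
}

#' Predict the binary class label
#'
#' A record is classified as recovered when its predicted probability is at
#' least the threshold (the boundary probability classifies as 1, an explicit
#' convention).
#'
#' @inheritParams predict_probability
#' @param threshold classification threshold in (0, 1); default 0.5.
#' @return integer vector of 0/1 labels.
#' @export
predict_class <- function(model, segments, threshold = 0.5) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly inside (0, 1)", call. = FALSE)
  }
  as.integer(predict_probability(model, segments) >= threshold)
}
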