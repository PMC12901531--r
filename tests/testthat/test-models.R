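test_that("every algorithm honours the probability-output contract", {
  coh <- default_cohort()
  train <- as.data.frame(coh)[coh$subject_id %in%
                                sprintf("S%02d", 1:14), ]
  test <- coh[!coh$subject_id %in% sprintf("S%02d", 1:14), ]
  for (alg in ALGORITHMS) {
    spec <- model_spec(alg, c("fdg", "lge", "wma"), seed = 9L)
    fit <- train_model(spec, train)
    p <- predict_probability(fit, test)
    expect_length(p, nrow(test))
    expect_true(all(p >= 0 & p <= 1), info = alg)
    # reproducible under the same seed
    fit2 <- train_model(model_spec(alg, c("fdg", "lge", "wma"), seed = 9L),
                        train)
    expect_identical(predict_probability(fit2, test), p, info = alg)
    # output order aligned with input order
    perm <- sample(nrow(test))
    expect_equal(predict_probability(fit, test[perm, ]), p[perm],
                 tolerance = 1e-12, info = alg)
    # class labels are thresholded probabilities, boundary -> 1
    expect_equal(predict_class(fit, test), as.integer(p >= 0.5), info = alg)
  }
  expect_error(predict_class(fit, test, threshold = 1), "threshold")
  expect_error(train_model(model_spec("LogReg", "lge"),
                           train[train$recovery == 0, ]), "single-class")
})

test_that("training-order permutation does not move deterministic predictions", {
  coh <- default_cohort()
  train <- as.data.frame(coh)
  test <- coh[1:20, ]
  for (alg in c("LogReg", "NBayes", "KNN")) {
    spec <- model_spec(alg, c("fdg", "lge"), seed = 4L)
    p1 <- predict_probability(train_model(spec, train), test)
    p2 <- predict_probability(train_model(spec, train[sample(nrow(train)), ]),
                              test)
    expect_equal(p1, p2, tolerance = 1e-9, info = alg)
  }
})

test_that("logistic models learn the separating direction", {
  df <- data.frame(
    subject_id = rep(c("A", "B", "C"), each = 2),
    segment_id = rep(1:2, 3),
    fdg = 0, wma_baseline = 1,
    recovery = c(1, 0, 1, 0, 1, 0),
    in_cto_territory = TRUE
  )
  df$lge <- 4 * df$recovery
  fit <- train_model(model_spec("LogReg", "lge"), as_cohort(df))
  expect_gt(stats::coef(fit$fit)[["lge"]], 0)
  # perfect-case variable: training accuracy 1 at threshold 0.5
  coh <- default_cohort()
  pf <- train_model(model_spec("LogReg", "sim_perfect"), as.data.frame(coh))
  expect_equal(predict_class(pf, coh), coh$recovery)
  expect_true(all(predict_probability(pf, coh)[coh$sim_perfect == 1] > 0.5))
})

test_that("MELogReg collapses to LogReg when clustering is absent", {
  cfg <- generator_config(subject_effect_sd = 0, seed = 31L)
  coh <- apply_inclusion_filter(generate_cohort(cfg))
  spec_me <- model_spec("MELogReg", c("fdg", "lge"), seed = 1L)
  spec_lr <- model_spec("LogReg", c("fdg", "lge"), seed = 1L)
  fit_me <- train_model(spec_me, coh)
  fit_lr <- train_model(spec_lr, coh)
  b_lr <- stats::coef(fit_lr$fit)
  se_lr <- sqrt(diag(stats::vcov(fit_lr$fit)))
  b_me <- lme4::fixef(fit_me$fit)
  expect_true(all(abs(b_me - b_lr) <= 2 * se_lr))
  # unseen subjects are predicted from the fixed effects alone
  unseen <- as.data.frame(coh[1:5, ])
  unseen$subject_id <- "ZZZ"
  eta <- b_me[1] + b_me["fdg"] * unseen$fdg + b_me["lge"] * unseen$lge
  expect_equal(predict_probability(fit_me, unseen), unname(plogis(eta)),
               tolerance = 1e-6)
})

test_that("KNN with k >= n on a balanced set votes 0.5 everywhere", {
  df <- data.frame(
    subject_id = rep(c("A", "B"), each = 3),
    segment_id = rep(1:3, 2),
    fdg = c(0, 1, 2, 2, 3, 4), lge = c(1, 2, 0, 3, 4, 2), wma_baseline = 1,
    recovery = c(1, 1, 1, 0, 0, 0),
    in_cto_territory = TRUE
  )
  fit <- train_model(model_spec("KNN", c("fdg", "lge"),
                                hyperparameters = list(knn_k = 50L)),
                     as_cohort(df))
  expect_equal(predict_probability(fit, as_cohort(df)), rep(0.5, 6))
  # boundary convention: probability 0.5 classifies as recovered
  expect_equal(predict_class(fit, as_cohort(df)), rep(1L, 6))
})

test_that("Gaussian NBayes matches an independently coded posterior", {
  df <- data.frame(
    subject_id = rep(c("A", "B"), each = 5),
    segment_id = rep(1:5, 2),
    fdg = c(3, 4, 3, 2, 4, 0, 1, 0, 2, 1),
    lge = c(0, 1, 1, 0, 2, 3, 4, 3, 2, 4),
    wma_baseline = 1,
    recovery = rep(c(1, 0), each = 5),
    in_cto_territory = TRUE
  )
  coh <- as_cohort(df)
  fit <- train_model(model_spec("NBayes", c("fdg", "lge")), coh)
  p_pkg <- predict_probability(fit, coh)
  # hand-rolled Gaussian class-conditionals with empirical priors
  post <- function(x) {
    lik <- sapply(c(0, 1), function(cls) {
      sub <- df[df$recovery == cls, ]
      prior <- nrow(sub) / nrow(df)
      prior * dnorm(x["fdg"], mean(sub$fdg), sd(sub$fdg)) *
        dnorm(x["lge"], mean(sub$lge), sd(sub$lge))
    })
    lik[2] / sum(lik)
  }
  p_hand <- apply(df[c("fdg", "lge")], 1, post)
  expect_equal(p_pkg, unname(p_hand), tolerance = 1e-9)
  # a record at the class-1 conditional modes is called recovered
  expect_gt(p_pkg[1], 0.5)
})

test_that("a constant-valued variable leaves LogReg predictions unchanged", {
  coh <- default_cohort()
  df <- as.data.frame(coh)
  df$wma_baseline <- 2L   # constant -> unidentifiable coefficient
  fit1 <- train_model(model_spec("LogReg", "lge"), df)
  fit2 <- train_model(model_spec("LogReg", c("lge", "wma")), df)
  expect_equal(predict_probability(fit1, df),
               suppressWarnings(predict_probability(fit2, df)),
               tolerance = 1e-9)
})
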