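test_that("clustered AUC equals exhaustive pair counting", {
  # frozen small instance: 4 positives x 4 negatives, clusters of size 2
  prob <- c(.9, .8, .7, .6, .4, .3, .2, .1)
  lab <- c(1, 1, 1, 0, 1, 0, 0, 0)
  cl <- rep(c("a", "b", "c", "d"), each = 2)
  res <- clustered_auc(prob, lab, cl)
  expect_equal(res$auc, 15 / 16)
  expect_equal(res$auc, oracle_auc(prob, lab))
  expect_equal(res$n_clusters, 4)
  expect_equal(c(res$n_pos, res$n_neg), c(4, 4))
  # fuzzed instances, including heavy ties
  set.seed(101)
  for (i in 1:80) {
    z <- random_auc_instance()
    expect_equal(clustered_auc(z$prob, z$labels, z$cluster)$auc,
                 oracle_auc(z$prob, z$labels), tolerance = 1e-12)
  }
  # conventions
  expect_equal(clustered_auc(lab, lab, cl)$auc, 1)
  expect_equal(clustered_auc(rep(0.3, 8), lab, cl)$auc, 0.5)
  expect_error(clustered_auc(prob, rep(1, 8), cl), "both classes")
  one <- clustered_auc(prob, lab, rep("x", 8))
  expect_false(one$se_defined)
  expect_true(is.na(one$se))
})

test_that("components SE reduces to the unclustered closed form for singletons", {
  set.seed(202)
  for (i in 1:40) {
    z <- random_auc_instance(singleton = TRUE)
    res <- clustered_auc(z$prob, z$labels, z$cluster)
    pos <- z$prob[z$labels == 1]
    neg <- z$prob[z$labels == 0]
    v10 <- sapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)))
    v01 <- sapply(neg, function(x) mean((pos > x) + 0.5 * (pos == x)))
    closed <- sqrt(var(v10) / length(pos) + var(v01) / length(neg))
    expect_equal(res$se, closed, tolerance = 1e-10)
  }
})

test_that("jackknife SE matches the delete-one-cluster oracle", {
  prob <- c(.9, .8, .7, .6, .4, .3, .2, .1)
  lab <- c(1, 1, 1, 0, 1, 0, 0, 0)
  cl <- rep(c("a", "b", "c", "d"), each = 2)
  res <- clustered_auc(prob, lab, cl, se_method = "jackknife")
  expect_equal(res$se, oracle_jackknife_se(prob, lab, cl), tolerance = 1e-6)
  set.seed(303)
  n_ok <- 0
  while (n_ok < 25) {
    z <- random_auc_instance()
    # oracle needs both classes to survive every cluster deletion
    viable <- all(sapply(unique(z$cluster), function(cc)
      length(unique(z$labels[z$cluster != cc])) == 2))
    if (!viable) next
    jk <- clustered_auc(z$prob, z$labels, z$cluster, se_method = "jackknife")
    expect_equal(jk$se, oracle_jackknife_se(z$prob, z$labels, z$cluster),
                 tolerance = 1e-6)
    n_ok <- n_ok + 1
  }
})

test_that("cluster duplication inflates the naive SE but not the clustered SE", {
  set.seed(404)
  z <- random_auc_instance(n_max = 20)
  base <- clustered_auc(z$prob, z$labels, z$cluster)
  dup <- clustered_auc(rep(z$prob, 2), rep(z$labels, 2), rep(z$cluster, 2))
  # duplicating every cluster's records leaves the clustered SE unchanged
  expect_equal(dup$se, base$se, tolerance = 1e-9)
  # while the naive singleton treatment shrinks by ~ sqrt(2)
  naive <- clustered_auc(z$prob, z$labels, seq_along(z$prob))
  naive_dup <- clustered_auc(rep(z$prob, 2), rep(z$labels, 2),
                             seq_len(2 * length(z$prob)))
  expect_lt(naive_dup$se, 0.8 * naive$se)
})

test_that("AUC percentage differences use the mean-of-ratios convention", {
  model <- data.frame(repetition = 1, fold = 1:2, auc = c(0.6, 0.5))
  ref <- data.frame(repetition = 1, fold = 1:2, auc = c(0.5, 0.5))
  d <- auc_percentage_difference(model, ref)
  expect_equal(d$mean_diff_pct, 10)                       # mean of {20, 0}
  expect_equal(d$se_folds_pct, sd(c(20, 0)) / sqrt(2))
  expect_equal(d$z_p, 2 * pnorm(-abs(10 / (sd(c(20, 0)) / sqrt(2)))))
  # identical model and reference
  same <- auc_percentage_difference(ref, ref)
  expect_equal(same$mean_diff_pct, 0)
  expect_equal(same$z_p, 1)
  # constant ratio: degenerate zero spread, p -> 0
  m10 <- data.frame(repetition = rep(1:5, each = 2), fold = rep(1:2, 5),
                    auc = 1.0)
  r10 <- transform(m10, auc = 0.5)
  big <- auc_percentage_difference(m10, r10)
  expect_equal(big$mean_diff_pct, 100)
  expect_true(big$degenerate)
  expect_equal(big$z_p, 0)
  expect_error(auc_percentage_difference(m10, transform(m10, auc = 0)),
               "zero")
})

test_that("combined 5x2 F-test: degeneracy, power, and validation", {
  coh <- default_cohort()
  specs <- list(ref = model_spec("LogReg", c("fdg", "lge")),
                perfect = model_spec("LogReg", "sim_perfect"))
  cv <- run_repeated_cv(coh, specs, cv_scheme(5, 2, base_seed = 13L))
  te <- function(m) cv$predictions[cv$predictions$model == m &
                                     cv$predictions$role == "test", ]
  # self-comparison: all differences zero, p = 1
  self <- combined_clustered_f_test(te("ref"), te("ref"))
  expect_true(self$degenerate)
  expect_equal(self$p, 1)
  # perfect control against the weak reference rejects
  ft <- combined_clustered_f_test(te("perfect"), te("ref"))
  expect_equal(ft$df, c(10, 5))
  expect_lt(ft$p, 0.05)
  # K != 2 is unsupported
  cv3 <- run_repeated_cv(coh, specs["ref"], cv_scheme(1, 3, base_seed = 3L))
  p3 <- cv3$predictions[cv3$predictions$role == "test", ]
  expect_error(combined_clustered_f_test(p3, p3), "K = 2")
  # mismatched fold membership is a pairing error
  shifted <- te("ref")
  shifted$fold <- 3 - shifted$fold
  expect_error(combined_clustered_f_test(te("perfect"), shifted),
               "matched-pair")
})

test_that("Cramer's V follows the classical chi-square formula", {
  x <- rep(c(0, 0, 1, 1), c(30, 10, 10, 30))
  y <- rep(c(0, 1, 0, 1), c(30, 10, 10, 30))
  expect_equal(cramers_v(x, y), 0.5)      # chi2 = 20, n = 80, V = sqrt(20/80)
  z <- sample(0:4, 400, replace = TRUE)
  expect_equal(cramers_v(z, z), 1)
  set.seed(7)
  expect_lt(cramers_v(sample(0:4, 4000, TRUE), sample(0:4, 4000, TRUE)),
            0.06)
  expect_warning(v0 <- cramers_v(rep(1, 10), sample(0:1, 10, TRUE)),
                 "degenerate")
  expect_equal(v0, 0)
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni_adjust(0.01, 5), 0.05)
  expect_equal(bonferroni_adjust(0.5, 40), 1)
  expect_equal(bonferroni_adjust(c(0.001, 0.02), 2), c(0.002, 0.04))
  expect_error(bonferroni_adjust(0.1, 0), "m must be")
})
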