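test_that("exact attributions match the permutation oracle", {
  coh <- default_cohort()
  bg <- as.data.frame(coh)[1:12, ]
  set.seed(55)
  for (alg in c("LogReg", "NBayes", "DecTree")) {
    fit <- train_model(model_spec(alg, c("fdg", "lge"), seed = 2L),
                       as.data.frame(coh))
    for (i in sample(nrow(coh), 3)) {
      inst <- coh[i, ]
      phi <- exact_shapley_values(fit, bg, inst)
      expect_equal(phi, oracle_shapley(fit, bg, inst), tolerance = 1e-8,
                   info = alg)
    }
  }
  # three-variable model too
  fit3 <- train_model(model_spec("LogReg", c("fdg", "lge", "wma"), seed = 2L),
                      as.data.frame(coh))
  phi3 <- exact_shapley_values(fit3, bg, coh[4, ])
  expect_equal(phi3, oracle_shapley(fit3, bg, coh[4, ]), tolerance = 1e-8)
})

test_that("efficiency, dummy and symmetry axioms hold", {
  coh <- default_cohort()
  bg <- as.data.frame(coh)[1:15, ]
  fit <- train_model(model_spec("LogReg", c("fdg", "lge"), seed = 3L),
                     as.data.frame(coh))
  for (i in c(2, 9, 30)) {
    inst <- coh[i, ]
    phi <- exact_shapley_values(fit, bg, inst)
    # efficiency: attributions sum to v(full) - v(empty)
    full <- bg
    full$fdg <- inst$fdg
    full$lge <- inst$lge
    v_full <- mean(predict_probability(fit, full))
    v_empty <- mean(predict_probability(fit, bg))
    expect_equal(sum(phi), v_full - v_empty, tolerance = 1e-8)
  }
  # dummy: a variable with an unidentifiable (dropped) coefficient gets 0
  const <- as.data.frame(coh)
  const$fdg <- 2L
  fit_d <- train_model(model_spec("LogReg", c("fdg", "lge"), seed = 3L), const)
  phi_d <- suppressWarnings(exact_shapley_values(fit_d, const[1:10, ],
                                                 const[3, ]))
  expect_equal(unname(phi_d["fdg"]), 0, tolerance = 1e-10)
  # symmetry: identically-behaving variables share the attribution
  sym <- as.data.frame(coh)
  sym$fdg <- sym$lge
  fit_s <- train_model(model_spec("NBayes", c("fdg", "lge"), seed = 3L), sym)
  phi_s <- exact_shapley_values(fit_s, sym[1:12, ], sym[5, ])
  expect_equal(unname(phi_s["fdg"]), unname(phi_s["lge"]), tolerance = 1e-8)
})

test_that("single-variable attribution is the deviation from the base rate", {
  coh <- default_cohort()
  bg <- as.data.frame(coh)[1:20, ]
  for (alg in c("LogReg", "RF")) {
    fit <- train_model(model_spec(alg, "lge", seed = 6L), as.data.frame(coh))
    inst <- coh[7, ]
    phi <- exact_shapley_values(fit, bg, inst)
    sub <- bg
    sub$lge <- inst$lge
    expected <- mean(predict_probability(fit, sub)) -
      mean(predict_probability(fit, bg))
    expect_equal(unname(phi["lge"]), expected, tolerance = 1e-10, info = alg)
  }
})

test_that("local mean tables average per populated score cell", {
  rec <- data.frame(lge = c(1, 1, 3))
  attr_m <- matrix(c(0.2, 0.4, -0.1), ncol = 1,
                   dimnames = list(NULL, "lge"))
  tab <- local_mean_shapley(attr_m, rec)
  expect_equal(tab$score, c(1, 3))
  expect_equal(tab$value, c(0.3, -0.1))
  expect_equal(tab$support, c(2, 1))
  # a fold with a single score level populates only that cell
  rec2 <- data.frame(lge = rep(2, 5))
  tab2 <- local_mean_shapley(matrix(0, 5, 1, dimnames = list(NULL, "lge")),
                             rec2)
  expect_equal(tab2$score, 2)
  expect_equal(tab2$value, 0)
})

test_that("global absolute aggregation is a mean of absolute cell values", {
  tab <- data.frame(repetition = 1, fold = 1,
                    variable = "lge", score = c(0, 4),
                    value = c(-0.1, 0.3), support = c(3, 2))
  g <- global_absolute_shapley(tab)
  expect_equal(g$mean, 0.2)          # mean(|-0.1|, |0.3|)
  expect_equal(g$se, 0)
  # support-weighted variant
  gw <- global_absolute_shapley(tab, support_weighted = TRUE)
  expect_equal(gw$mean, (0.1 * 3 + 0.3 * 2) / 5)
  # constant folds: zero SE; sign-invariance of the aggregate
  many <- do.call(rbind, lapply(1:5, function(r)
    transform(tab, repetition = r, value = c(0.2, -0.2))))
  gm <- global_absolute_shapley(many)
  expect_equal(gm$mean, 0.2)
  expect_equal(gm$se, 0)
  flipped <- transform(many, value = -value)
  expect_equal(global_absolute_shapley(flipped)$mean, gm$mean)
})

test_that("corrected resampled t-test matches direct arithmetic", {
  d <- c(12, 8, 15, 5, 10, 10, 14, 6, 9, 11)   # per-fold % differences
  ref <- data.frame(repetition = rep(1:5, each = 2), fold = rep(1:2, 5),
                    value = 1)
  model <- transform(ref, value = 1 + d / 100)
  res <- shapley_percentage_difference(model, ref)
  se_hand <- sqrt((1 / 10 + 1) * var(d))        # K = 2 -> ratio 1
  expect_equal(res$mean_diff_pct, mean(d))
  expect_equal(res$t_statistic, mean(d) / se_hand)
  expect_equal(res$t_p, 2 * pt(-abs(mean(d) / se_hand), df = 9))
  # identical model and reference
  same <- shapley_percentage_difference(ref, ref)
  expect_equal(same$mean_diff_pct, 0)
  expect_equal(same$t_p, 1)
  expect_true(same$degenerate)
  # constant non-zero differences: degenerate variance, p -> 0
  up <- transform(ref, value = 1.5)
  const <- shapley_percentage_difference(up, ref)
  expect_equal(const$mean_diff_pct, 50)
  expect_true(const$degenerate)
  expect_equal(const$t_p, 0)
  expect_error(shapley_percentage_difference(model, transform(ref, value = 0)),
               "zero")
})
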