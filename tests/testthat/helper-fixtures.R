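# shared fixtures, built in code and memoised per test session

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env, inherits = FALSE)) {
    assign(key, expr, envir = .fixture_env)
  }
  get(key, envir = .fixture_env, inherits = FALSE)
}

# small handmade cohort: 4 subjects, each with both classes
toy_cohort <- function() {
  as_cohort(data.frame(
    subject_id = rep(c("S01", "S02", "S03", "S04"), each = 4),
    segment_id = rep(1:4, times = 4),
    fdg = c(0, 1, 2, 3, 1, 2, 3, 4, 0, 0, 1, 2, 2, 3, 4, 4),
    lge = c(1, 1, 2, 4, 0, 2, 3, 4, 1, 0, 1, 3, 2, 2, 3, 4),
    wma_baseline = c(1, 2, 2, 3, 1, 1, 2, 4, 2, 1, 1, 3, 2, 3, 3, 4),
    recovery = c(1, 0, 0, 0, 1, 1, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0),
    in_cto_territory = TRUE,
    stringsAsFactors = FALSE
  ))
}

# the default synthetic study cohort (filtered, with simulation variables)
default_cohort <- function(seed = 3L) {
  memo(paste0("cohort_", seed), {
    coh <- apply_inclusion_filter(generate_cohort(generator_config(seed = seed)))
    add_simulation_variables(coh, seed = seed)
  })
}

# perfect/flawed sanity study: reference + simulation models, 5x2, with the
# explainability track
perfect_study <- function() {
  memo("perfect_study", {
    run_full_comparison(
      default_cohort(), cv_scheme(5, 2, base_seed = 42L),
      variable_sets = list(), include_simulations = TRUE,
      compute_shapley = TRUE
    )
  })
}

# independent pair-counting AUC oracle (exhaustive enumeration, ties = 1/2)
oracle_auc <- function(prob, labels) {
  pos <- prob[labels == 1]
  neg <- prob[labels == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# independent delete-one-cluster jackknife SE oracle
oracle_jackknife_se <- function(prob, labels, cluster) {
  cls <- unique(cluster)
  I <- length(cls)
  theta <- sapply(cls, function(cc) {
    keep <- cluster != cc
    oracle_auc(prob[keep], labels[keep])
  })
  sqrt((I - 1) / I * sum((theta - mean(theta))^2))
}

# random small clustered scoring instance for fuzzing
random_auc_instance <- function(n_max = 30, singleton = FALSE) {
  n <- sample(4:n_max, 1)
  labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
  prob <- round(runif(n), sample(c(1, 2, 6), 1))  # coarse rounding forces ties
  cluster <- if (singleton) {
    as.character(seq_len(n))
  } else {
    as.character(sample(ceiling(n / 3), n, replace = TRUE))
  }
  list(prob = prob, labels = labels, cluster = cluster)
}

# independent Shapley oracle: average marginal contribution over all
# variable permutations, coalition values computed by explicit loops
oracle_shapley <- function(model, background, instance) {
  vars <- model$spec$variables
  m <- length(vars)
  bg <- as.data.frame(background)
  v <- function(S) {
    rows <- bg
    for (vn in S) {
      col <- if (vn == "wma") "wma_baseline" else vn
      rows[[col]] <- as.data.frame(instance)[[col]][1]
    }
    mean(predict_probability(model, rows))
  }
  phi <- stats::setNames(numeric(m), vars)
  perms <- if (m == 1) list(1L) else asplit(gtools_permutations(m), 1)
  for (p in perms) {
    S <- character(0)
    for (j in p) {
      phi[vars[j]] <- phi[vars[j]] + v(c(S, vars[j])) - v(S)
      S <- c(S, vars[j])
    }
  }
  phi / length(perms)
}

# all permutations of 1:m (tiny m), without external dependencies
gtools_permutations <- function(m) {
  if (m == 1) return(matrix(1L))
  sub <- gtools_permutations(m - 1)
  out <- NULL
  for (i in seq_len(m)) {
    rest <- setdiff(seq_len(m), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}
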