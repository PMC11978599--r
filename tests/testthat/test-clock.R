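make_proteins <- function(X) {
  colnames(X) <- sprintf("G%04d", seq_len(ncol(X)))
  dplyr::bind_cols(tibble::tibble(participant = sprintf("P%05d",
                                                        seq_len(nrow(X)))),
                   tibble::as_tibble(X))
}

test_that("clock metrics match their closed forms", {
  set.seed(1)
  age <- runif(200, 40, 70)
  perfect <- evaluate_clock(age, age)
  expect_equal(perfect$r_squared, 1)
  expect_equal(perfect$pearson_r, 1)
  expect_equal(perfect$rmse, 0)

  shifted <- evaluate_clock(age + 5, age)
  expect_equal(shifted$pearson_r, 1)
  expect_equal(shifted$rmse, 5)
  expect_equal(shifted$r_squared, 1 - 200 * 25 / sum((age - mean(age))^2))

  null <- evaluate_clock(rep(mean(age), 200), age)
  expect_equal(null$r_squared, 0)
  expect_equal(null$rmse, sqrt(mean((age - mean(age))^2)))
  expect_true(is.na(null$pearson_r))

  sub <- evaluate_clock(age, age,
                        subgroups = data.frame(g = rep(c("a", "b"), 100),
                                               tiny = c("x", rep("y", 199))))
  expect_setequal(sub$subgroup, c("overall", "g=a", "g=b", "tiny=x", "tiny=y"))
  expect_true(sub$small_sample[sub$subgroup == "tiny=x"])
})

test_that("a perfect-signal column yields near-perfect out-of-fold accuracy", {
  set.seed(2)
  age <- runif(500, 40, 70)
  X <- cbind(age, matrix(rnorm(500 * 4), 500))
  clk <- fit_clock(make_proteins(X), age, n_folds = 5, seed = 1)
  expect_gt(glance(clk)$r_squared, 0.95)
})

test_that("pure-noise proteins give no out-of-fold skill (leakage guard)", {
  set.seed(3)
  age <- runif(2000, 40, 70)
  X <- matrix(rnorm(2000 * 20), 2000)
  clk <- fit_clock(make_proteins(X), age, n_folds = 5, seed = 1)
  expect_lte(glance(clk)$r_squared, 0.05)
})

test_that("the clock is deterministic and validates its inputs", {
  set.seed(4)
  age <- runif(150, 40, 70)
  prot <- make_proteins(cbind(age + rnorm(150), rnorm(150)))
  c1 <- fit_clock(prot, age, n_folds = 3, seed = 9)
  c2 <- fit_clock(prot, age, n_folds = 3, seed = 9)
  expect_identical(c1$predictions$predicted_age, c2$predictions$predicted_age)
  # fold bookkeeping partitions the cohort
  expect_setequal(c1$fold_assignment$participant, prot$participant)
  expect_equal(sort(unique(c1$fold_assignment$fold)), 1:3)

  expect_error(fit_clock(prot, rep(50, 150)), "constant age")
  expect_error(fit_clock(prot, age, n_folds = 1), "at least 2")
  expect_error(fit_clock(prot[1:20, ], age[1:20], n_folds = 5), "per fold")
  prot$G0001[3] <- NA
  expect_error(fit_clock(prot, age), "missing")
})

test_that("Boruta confirms a planted signal and rejects pure noise", {
  set.seed(5)
  n <- 500
  y <- runif(n, 40, 70)
  X <- cbind(y + rnorm(n, 0, 0.5), matrix(rnorm(n * 20), n))
  prot <- make_proteins(X)
  sel <- boruta_select(prot, y, seed = 1)
  expect_true("G0001" %in% sel$confirmed)
  expect_gte(length(sel$rejected), 15)
  # three-way partition is exhaustive and disjoint
  all_feats <- setdiff(names(prot), "participant")
  expect_setequal(c(sel$confirmed, sel$rejected, sel$tentative), all_feats)
  expect_equal(length(sel$confirmed) + length(sel$rejected) +
                 length(sel$tentative), length(all_feats))
})

test_that("Boruta under the null stays within its false-positive budget", {
  # Null here means population-independent features; a feature whose sample
  # correlation with y happens to be large is still (correctly) flagged by a
  # shadow-based selector, so the budget is the per-feature alpha level:
  # 8 seeds x 10 features x alpha 0.05 = 4 expected worst-case confirmations.
  confirmed <- 0L
  for (s in 1:8) {
    set.seed(400 + s)
    y <- rnorm(300)
    X <- matrix(rnorm(300 * 10), 300)
    sel <- boruta_select(make_proteins(X), y, max_iter = 40, seed = s)
    confirmed <- confirmed + length(sel$confirmed)
  }
  expect_lte(confirmed, 4L)
})

test_that("borderline features stay tentative at a small iteration cap", {
  set.seed(6)
  n <- 400
  y <- runif(n, 40, 70)
  # moderate signal among noise, too few iterations to decide everything
  X <- cbind(y + rnorm(n, 0, 8), y + rnorm(n, 0, 12),
             matrix(rnorm(n * 6), n))
  sel <- boruta_select(make_proteins(X), y, max_iter = 10, seed = 2)
  all_feats <- sprintf("G%04d", 1:8)
  expect_setequal(c(sel$confirmed, sel$rejected, sel$tentative), all_feats)
})

test_that("Shapley importance is additive and finds the dominant protein", {
  set.seed(7)
  n <- 600
  age <- runif(n, 40, 70)
  b <- c(1, rep(0.1, 5))
  X <- sapply(b, function(bj) bj * age + rnorm(n, 0, 0.5))
  prot <- make_proteins(X)
  clk <- fit_clock(prot, age, n_folds = 3, seed = 1)
  imp <- shapley_importance(clk, prot)
  expect_equal(imp$protein[1], "G0001")
  # additivity, at the single-precision resolution of the tree backend
  expect_lt(attr(imp, "additivity_error"), 1e-4)
  expect_setequal(imp$protein, clk$selected_proteins)
})

test_that("duplicated features share the attribution of the original", {
  set.seed(8)
  n <- 500
  age <- runif(n, 40, 70)
  x1 <- age + rnorm(n, 0, 1)
  x2 <- 0.3 * age + rnorm(n, 0, 1)
  base <- make_proteins(cbind(x1, x2))
  dup <- make_proteins(cbind(x1, x2, x1))
  clk_base <- fit_clock(base, age, n_folds = 3, seed = 2)
  clk_dup <- fit_clock(dup, age, n_folds = 3, seed = 2)
  imp_base <- shapley_importance(clk_base, base)
  imp_dup <- shapley_importance(clk_dup, dup)
  single <- imp_base$mean_abs_shap[imp_base$protein == "G0001"]
  pair <- sum(imp_dup$mean_abs_shap[imp_dup$protein %in% c("G0001", "G0003")])
  expect_lt(abs(pair - single) / single, 0.2)
})

test_that("refitting on Boruta-confirmed proteins does not hurt accuracy", {
  cfg <- sim_config(n_participants = 1200L, missing_rate = 0, seed = 13L)
  sim <- simulate_cohort(cfg)
  age <- sim$cohort$age
  sel <- boruta_select(sim$proteins, age, seed = 3)
  expect_gte(length(sel$confirmed), 5)
  clk_all <- fit_clock(sim$proteins, age, n_folds = 5, seed = 4)
  clk_sel <- fit_clock(sim$proteins[c("participant", sel$confirmed)], age,
                       n_folds = 5, seed = 4)
  expect_lte(glance(clk_sel)$rmse, glance(clk_all)$rmse * 1.05)
})
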