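default_clock_params <- function() {
  list(max_depth = 6L, eta = 0.05, nrounds = 500L, early_stopping_rounds = 25L,
       min_child_weight = 5, subsample = 1, colsample_bytree = 1,
       tree_method = "hist", nthread = 1L)
}

as_protein_matrix <- function(proteins) {
  prots <- setdiff(names(proteins), "participant")
  X <- as.matrix(proteins[prots])
  if (anyNA(X)) abort("protein matrix contains missing values; impute first")
  storage.mode(X) <- "double"
  X
}

train_booster <- function(X, y, params, seed, valid_frac = 0.2) {
  # internal validation split (within the training data) for early stopping
  set.seed(seed)
  n <- nrow(X)
  n_val <- max(2L, floor(valid_frac * n))
  val_idx <- sample.int(n, n_val)
  dtrain <- xgboost::xgb.DMatrix(X[-val_idx, , drop = FALSE],
                                 label = y[-val_idx])
  dval <- xgboost::xgb.DMatrix(X[val_idx, , drop = FALSE], label = y[val_idx])
  xgb_params <- list(objective = "reg:squarederror",
                     max_depth = params$max_depth, eta = params$eta,
                     min_child_weight = params$min_child_weight,
                     subsample = params$subsample,
                     colsample_bytree = params$colsample_bytree,
                     tree_method = params$tree_method, nthread = params$nthread,
                     seed = seed)
  xgboost::xgb.train(params = xgb_params, data = dtrain,
                     nrounds = params$nrounds,
                     evals = list(val = dval),
                     early_stopping_rounds = params$early_stopping_rounds,
                     verbose = 0)
}

#' Fit a proteomic age clock with out-of-fold predictions
#'
#' Trains gradient-boosted regression trees of chronological age on protein
#' abundances under k-fold cross-fitting: each participant's predicted age
#' comes from an ensemble trained without them, so downstream brain-age-gap
#' analyses are free of in-sample optimism.
#'
#' @param proteins Tibble: `participant` plus complete (imputed) protein
#'   columns.
#' @param age Chronological ages, aligned with `proteins` rows.
#' @param params Learner hyperparameters; see `default_clock_params()`
#'   (shallow trees, learning rate 0.05, up to 500 rounds with early stopping
#'   on an internal validation split).
#' @param n_folds Number of cross-fitting folds.
#' @param seed Integer seed controlling fold assignment and tree fitting.
#' @return Object of class `brain_age_clock`: fold models, fold assignment,
#'   gain-based importance, and `$predictions` with out-of-fold
#'   `predicted_age`.
#' @export
fit_clock <- function(proteins, age, params = list(), n_folds = 5L,
                      seed = 1L) {
  params <- modifyList(default_clock_params(), params)
  X <- as_protein_matrix(proteins)
  n <- nrow(X)
  if (length(age) != n) abort("`age` must align with `proteins` rows")
  if (sd(age) == 0) abort("constant age vector: R-squared undefined")
  if (n_folds < 2L) abort("`n_folds` must be at least 2")
  if (n < 10L * n_folds) abort("need at least 10 participants per fold")

  set.seed(seed)
  fold <- sample(rep(seq_len(n_folds), length.out = n))
  predicted <- numeric(n)
  boosters <- vector("list", n_folds)
  for (k in seq_len(n_folds)) {
    tr <- fold != k
    boosters[[k]] <- train_booster(X[tr, , drop = FALSE], age[tr], params,
                                   seed = seed + k)
    predicted[!tr] <- predict(boosters[[k]],
                              xgboost::xgb.DMatrix(X[!tr, , drop = FALSE]))
  }
  importance <- gain_importance(boosters, colnames(X))
  ids <- if ("participant" %in% names(proteins)) proteins$participant
         else as.character(seq_len(n))
  structure(list(
    selected_proteins = colnames(X),
    params = params, seed = seed, n_folds = n_folds,
    fold_assignment = tibble::tibble(participant = ids, fold = fold),
    boosters = boosters,
    importance = importance,
    predictions = tibble::tibble(participant = ids, age = age,
                                 predicted_age = predicted, fold = fold)
  ), class = "brain_age_clock")
}

# mean gain per feature across fold ensembles; absent features get 0
gain_importance <- function(boosters, features) {
  gains <- purrr::map(boosters, function(b) {
    imp <- xgboost::xgb.importance(model = b)
    setNames(imp$Gain, imp$Feature)[features]
  })
  g <- rowMeans(do.call(cbind, purrr::map(gains, ~ ifelse(is.na(.x), 0, .x))))
  tibble::tibble(protein = features, gain = unname(g)) |>
    dplyr::arrange(dplyr::desc(.data$gain), .data$protein)
}

#' Predict age for new samples from a fitted clock
#'
#' Averages the per-fold ensembles (the standard cross-fitting predictor for
#' data outside the training cohort).
#'
#' @param object A `brain_age_clock`.
#' @param new_proteins Tibble with the clock's protein columns.
#' @param ... Unused.
#' @return Numeric vector of predicted ages.
#' @export
predict.brain_age_clock <- function(object, new_proteins, ...) {
  missing_cols <- setdiff(object$selected_proteins, names(new_proteins))
  if (length(missing_cols) > 0) abort("new data lacks clock proteins")
  X <- as_protein_matrix(new_proteins[object$selected_proteins])
  dm <- xgboost::xgb.DMatrix(X)
  rowMeans(do.call(cbind, purrr::map(object$boosters, ~ predict(.x, dm))))
}

#' @export
#' @method tidy brain_age_clock
tidy.brain_age_clock <- function(x, ...) x$importance

#' @export
#' @method glance brain_age_clock
glance.brain_age_clock <- function(x, ...) {
  m <- evaluate_clock(x$predictions$predicted_age, x$predictions$age)
  tibble::tibble(n = nrow(x$predictions), n_proteins =
                   length(x$selected_proteins), n_folds = x$n_folds,
                 r_squared = m$r_squared, pearson_r = m$pearson_r,
                 rmse = m$rmse)
}

#' Boruta all-relevant feature selection with shadow features
#'
#' Each iteration appends a column-wise permuted ("shadow") copy of every
#' feature, fits a gradient-boosted learner, and scores a "hit" for every
#' real feature whose gain importance exceeds the maximum shadow importance.
#' After each iteration the hit counts are tested against Binomial(iter, 0.5)
#' two-sided with Bonferroni correction across the original features: features
#' significantly above chance are confirmed, significantly below are rejected
#' (and removed from subsequent fits), and anything undecided at `max_iter`
#' stays tentative.
#'
#' @param X Matrix or tibble of complete features.
#' @param y Numeric response.
#' @param max_iter Maximum shadow iterations (at least 10).
#' @param alpha Two-sided significance level before Bonferroni correction.
#' @param seed Integer seed.
#' @param learner_params Overrides for the internal learner (kept light:
#'   depth-3 trees, 80 rounds).
#' @return List with character vectors `confirmed`, `rejected`, `tentative`
#'   (an exhaustive, disjoint partition of the features) and a `history`
#'   tibble of hit counts.
#' @export
boruta_select <- function(X, y, max_iter = 100L, alpha = 0.05, seed = 1L,
                          learner_params = list()) {
  if (is.data.frame(X)) X <- as_protein_matrix(X)
  if (ncol(X) < 2L) abort("Boruta needs at least 2 features")
  if (max_iter < 10L) abort("`max_iter` must be at least 10")
  params <- modifyList(list(max_depth = 3L, eta = 0.1, nrounds = 80L,
                            min_child_weight = 5, tree_method = "hist",
                            nthread = 1L), learner_params)
  features <- colnames(X)
  m <- length(features)
  status <- setNames(rep("tentative", m), features)
  hits <- setNames(integer(m), features)
  tested <- setNames(integer(m), features)
  set.seed(seed)
  for (iter in seq_len(max_iter)) {
    active <- features[status != "rejected"]
    Xa <- X[, active, drop = FALSE]
    shadow <- apply(Xa, 2, sample)
    colnames(shadow) <- paste0(".shadow_", active)
    dm <- xgboost::xgb.DMatrix(cbind(Xa, shadow), label = y)
    bst <- xgboost::xgb.train(
      params = list(objective = "reg:squarederror", max_depth = params$max_depth,
                    eta = params$eta, min_child_weight = params$min_child_weight,
                    tree_method = params$tree_method, nthread = params$nthread,
                    seed = seed + iter),
      data = dm, nrounds = params$nrounds, verbose = 0)
    imp <- xgboost::xgb.importance(model = bst)
    gain <- setNames(rep(0, ncol(Xa) * 2),
                     c(active, colnames(shadow)))
    gain[imp$Feature] <- imp$Gain
    max_shadow <- max(gain[colnames(shadow)])
    undecided <- features[status == "tentative"]
    hit_now <- gain[undecided] > max_shadow
    hits[undecided] <- hits[undecided] + as.integer(hit_now)
    tested[undecided] <- tested[undecided] + 1L
    # two-sided binomial decision, Bonferroni across all original features
    thr <- alpha / m
    for (f in undecided) {
      p_hi <- pbinom(hits[f] - 1L, tested[f], 0.5, lower.tail = FALSE)
      p_lo <- pbinom(hits[f], tested[f], 0.5)
      if (2 * p_hi < thr) status[f] <- "confirmed"
      else if (2 * p_lo < thr) status[f] <- "rejected"
    }
    if (!any(status == "tentative")) break
  }
  list(
    confirmed = features[status == "confirmed"],
    rejected = features[status == "rejected"],
    tentative = features[status == "tentative"],
    history = tibble::tibble(feature = features, hits = unname(hits),
                             iterations = unname(tested),
                             status = unname(status))
  )
}

#' Shapley-value importance of a fitted clock
#'
#' Computes exact tree-path Shapley attributions for every participant from
#' the fold model that did not see them, then summarizes each protein by the
#' mean absolute attribution. Attributions are additive: per participant they
#' sum (with the base value) to the out-of-fold prediction, up to the
#' single-precision arithmetic of the tree backend.
#'
#' @param model A `brain_age_clock`.
#' @param proteins The tibble the clock was fitted on.
#' @return Tibble `protein`, `mean_abs_shap`, sorted decreasing with
#'   lexicographic tie-break, plus an `additivity_error` attribute (max
#'   absolute deviation of sum-of-attributions from prediction).
#' @export
shapley_importance <- function(model, proteins) {
  if (!all(model$selected_proteins %in% names(proteins))) {
    abort("protein columns do not match the fitted clock")
  }
  X <- as_protein_matrix(proteins[model$selected_proteins])
  fold <- model$fold_assignment$fold
  if (length(fold) != nrow(X)) abort("row count does not match the fitted clock")
  contrib <- matrix(NA_real_, nrow(X), ncol(X) + 1L)
  pred <- numeric(nrow(X))
  for (k in seq_len(model$n_folds)) {
    idx <- fold == k
    dm <- xgboost::xgb.DMatrix(X[idx, , drop = FALSE])
    contrib[idx, ] <- predict(model$boosters[[k]], dm, predcontrib = TRUE)
    pred[idx] <- predict(model$boosters[[k]], dm)
  }
  add_err <- max(abs(rowSums(contrib) - pred))
  imp <- colMeans(abs(contrib[, seq_len(ncol(X)), drop = FALSE]))
  out <- tibble::tibble(protein = model$selected_proteins,
                        mean_abs_shap = unname(imp)) |>
    dplyr::arrange(dplyr::desc(.data$mean_abs_shap), .data$protein)
  attr(out, "additivity_error") <- add_err
  out
}

#' Clock performance metrics, overall and by subgroup
#'
#' Computes Pearson's correlation, R-squared (1 - SSE/SST against the
#' subgroup's own mean age) and RMSE, overall and within each level of the
#' supplied subgroup labels. Subgroups with fewer than 10 members are flagged.
#'
#' @param predicted,age Equal-length numeric vectors.
#' @param subgroups Optional data frame / tibble of label columns aligned with
#'   the vectors.
#' @return Tibble: subgroup ("overall" or "var=level"), n, pearson_r,
#'   r_squared, rmse, small_sample.
#' @export
evaluate_clock <- function(predicted, age, subgroups = NULL) {
  if (length(predicted) != length(age)) abort("vectors must be equal length")
  one <- function(p, a, label) {
    sse <- sum((a - p)^2)
    sst <- sum((a - mean(a))^2)
    tibble::tibble(
      subgroup = label, n = length(a),
      pearson_r = if (length(a) > 1 && sd(p) > 0 && sd(a) > 0) cor(p, a)
                  else NA_real_,
      r_squared = 1 - sse / sst,
      rmse = sqrt(mean((a - p)^2)),
      small_sample = length(a) < 10L
    )
  }
  out <- one(predicted, age, "overall")
  if (!is.null(subgroups)) {
    for (v in names(subgroups)) {
      lv <- split(seq_along(age), subgroups[[v]])
      for (l in names(lv)) {
        i <- lv[[l]]
        out <- dplyr::bind_rows(out, one(predicted[i], age[i],
                                         paste0(v, "=", l)))
      }
    }
  }
  out
}
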