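# Internal and external model validation.
#
# q2 (leave-one-out): each training compound is held out in turn, the model
# refit on the rest, and the held-out activity predicted; q2 = 1 -
# PRESS / sum((y - ybar_train)^2). pred_r2 is the external analogue over the
# test set with the *training-set* mean in the denominator. Y-randomization
# refits the whole pipeline on permuted activities and summarizes the true
# statistic's outlyingness as a Z-score.

#' Model recipe for refitting during validation
#'
#' Bundles the selection and PLS settings that validation routines need to
#' refit models. By default the descriptor selection is frozen from the full
#' training fit and only the coefficients are refit in each leave-one-out
#' fold; `reselect = TRUE` switches to the stricter reselect-per-fold mode.
#'
#' @param selected character vector of descriptor names (frozen selection).
#' @param n_components latent components for refits.
#' @param max_descriptors,max_components settings used when reselection is
#'   requested (randomization always reselects).
#' @param reselect logical; rerun stepwise selection inside each LOO fold.
#' @export
model_recipe <- function(selected, n_components = length(selected),
                         max_descriptors = 4L, max_components = 4L,
                         reselect = FALSE) {
  structure(list(selected = selected, n_components = as.integer(n_components),
                 max_descriptors = as.integer(max_descriptors),
                 max_components = as.integer(max_components),
                 reselect = isTRUE(reselect)),
            class = "model_recipe")
}

#' Prediction set
#'
#' Pairs of actual and predicted activities plus the reference mean used in
#' the denominator of r2-type statistics.
#'
#' @param actual,predicted numeric vectors of equal length.
#' @param reference_mean mean activity of the training set.
#' @export
prediction_set <- function(actual, predicted, reference_mean = mean(actual)) {
  stopifnot(length(actual) == length(predicted), all(is.finite(actual)),
            all(is.finite(predicted)))
  structure(list(actual = as.numeric(actual), predicted = as.numeric(predicted),
                 reference_mean = as.numeric(reference_mean)),
            class = "prediction_set")
}

fit_on <- function(X, y, recipe, train_mean) {
  f <- pls_nipals(X, y, min(recipe$n_components, ncol(X), nrow(X) - 1L))
  qsar_model(colnames(X), f$coef, f$intercept, max(f$ncomp, 1L), train_mean)
}

#' Leave-one-out cross-validated q2
#'
#' @param m descriptor_matrix.
#' @param train split_spec (training size >= 3).
#' @param recipe [model_recipe()].
#' @return q2 value with the LOO predictions (named by compound) in the
#'   `predictions` attribute.
#' @export
q_squared_loo <- function(m, train, recipe) {
  tr <- training_matrix(m, train)
  n <- nrow(tr$X)
  if (n < 3) stop("LOO validation needs at least 3 training compounds")
  ybar <- mean(tr$y)
  sst <- sum((tr$y - ybar)^2)
  if (sst < 1e-24) stop("constant training activities: q2 undefined")
  pred <- numeric(n)
  for (i in seq_len(n)) {
    Xi <- tr$X[-i, , drop = FALSE]; yi <- tr$y[-i]
    sel <- if (recipe$reselect) {
      mi <- descriptor_matrix(train$train_ids[-i], m$descriptors, Xi, yi)
      stepwise_forward_select(mi, split_spec(train$train_ids[-i]),
                              recipe$max_descriptors)
    } else recipe$selected
    fit <- fit_on(Xi[, sel, drop = FALSE], yi, recipe, ybar)
    pred[i] <- predict(fit, tr$X[i, sel, drop = FALSE])
  }
  q2 <- 1 - sum((tr$y - pred)^2) / sst
  attr(q2, "predictions") <- stats::setNames(pred, train$train_ids)
  q2
}

#' External predictive r2 (pred_r2)
#'
#' 1 - sum_test((y - yhat)^2) / sum_test((y - ybar_train)^2). The
#' denominator deliberately uses the training-set mean activity, not the
#' test mean.
#'
#' @param model qsar_model (its `training_mean_activity` is the reference).
#' @param m descriptor_matrix containing the test compounds.
#' @param test split_spec with nonempty `test_ids`.
#' @return pred_r2 with predictions in the `predictions` attribute.
#' @export
pred_r_squared <- function(model, m, test) {
  ids <- test$test_ids
  if (length(ids) == 0) stop("empty test set")
  idx <- match(ids, m$compound_ids)
  if (anyNA(idx)) stop("test ids not in matrix: ", paste(ids[is.na(idx)], collapse = ", "))
  y <- unname(m$activities[idx])
  yhat <- predict(model, m$values[idx, , drop = FALSE])
  ybar <- model$training_mean_activity
  sst <- sum((y - ybar)^2)
  if (sst < 1e-24) stop("zero denominator: test activities all equal the training mean")
  out <- 1 - sum((y - yhat)^2) / sst
  attr(out, "predictions") <- stats::setNames(yhat, ids)
  out
}

#' Fit statistics: r2, standard error, F-test
#'
#' r2 = 1 - SSE/SST on the fitted set; se = sqrt(SSE / (n - k - 1));
#' F = ((SST - SSE)/k) / (SSE/(n - k - 1)). A perfect fit reports F = Inf.
#'
#' @param p [prediction_set()].
#' @param k number of descriptors in the model.
#' @return list with `r2`, `se`, `f_test`, `degrees_of_freedom`.
#' @export
fit_statistics <- function(p, k) {
  n <- length(p$actual)
  if (n <= k + 1) stop("need n > k + 1 observations (n = ", n, ", k = ", k, ")")
  sse <- sum((p$actual - p$predicted)^2)
  sst <- sum((p$actual - mean(p$actual))^2)
  df <- n - k - 1L
  r2 <- 1 - sse / sst
  se <- sqrt(sse / df)
  f <- if (sse < 1e-24) Inf else ((sst - sse) / k) / (sse / df)
  list(r2 = r2, se = se, f_test = f, degrees_of_freedom = df)
}

#' Percent area under the standard normal curve left of z
#'
#' @param z finite numeric.
#' @return 100 * pnorm(z), rounded to 2 decimals.
#' @export
normal_area_percent <- function(z) {
  stopifnot(all(is.finite(z)))
  round(100 * stats::pnorm(z), 2)
}

#' Y-randomization test
#'
#' Training activities are randomly permuted over the training compounds
#' (seeded); for each permutation the descriptor selection is rerun and the
#' model refit, recording r2, LOO q2 and (when a test set is given)
#' pred_r2. Each observed statistic h is summarized as
#' Z = (h - mu) / sigma over the random-model distribution, together with
#' the best random value and the empirical one-sided p-value
#' (#random >= h + 1) / (n_permutations + 1).
#'
#' @param m descriptor_matrix.
#' @param train split_spec.
#' @param recipe model_recipe (used for the observed statistics; random
#'   models always reselect their own descriptors).
#' @param n_permutations number of permutations (>= 10; default 100).
#' @param seed integer RNG seed.
#' @param test optional split_spec for random-model pred_r2.
#' @param strict_cv compute every q2 in the comparison — observed and
#'   random — with reselect-per-fold leave-one-out (default FALSE).
#'   Cross-validating after selecting descriptors on the full set inflates
#'   q2 on permuted data (selection bias), so under the default protocol
#'   random models can score well above zero and the honest summary of
#'   separation is the empirical p-value. The strict mode removes that
#'   bias from both sides, at the price of a heavy-tailed random
#'   distribution (occasional wildly negative q2) that can deflate the
#'   Z-score on large descriptor pools; use it when the question is
#'   "does the pipeline hallucinate predictivity from pure noise".
#' @return named list of `randomization_result` (class) per statistic, each
#'   with `h`, `mu`, `sigma`, `z_score`, `best`, `p_value`, `values`.
#' @export
y_randomization <- function(m, train, recipe, n_permutations = 100L, seed = 42L,
                            test = NULL, strict_cv = FALSE) {
  stopifnot(n_permutations >= 10)
  tr <- training_matrix(m, train)
  # observed statistics under the supplied recipe
  model <- fit_pls(m, train, recipe$selected,
                   max_components = recipe$n_components)
  h_r2 <- fit_statistics(prediction_set(
    tr$y, predict(model, tr$X[, recipe$selected, drop = FALSE])),
    k = length(recipe$selected))$r2
  q2_recipe <- function(rec) {
    if (strict_cv) model_recipe(rec$selected, rec$n_components,
                                max_descriptors = rec$max_descriptors,
                                max_components = rec$max_components,
                                reselect = TRUE)
    else rec
  }
  h_q2 <- as.numeric(q_squared_loo(m, train, q2_recipe(recipe)))
  h_pred <- if (!is.null(test) && length(test$test_ids) > 0)
    as.numeric(pred_r_squared(model, m, test)) else NULL

  ids <- train$train_ids
  idx <- match(ids, m$compound_ids)
  stats_mat <- matrix(NA_real_, n_permutations, 3,
                      dimnames = list(NULL, c("r2", "q2", "pred_r2")))
  set.seed(seed)
  perms <- replicate(n_permutations, sample(length(ids)))
  for (b in seq_len(n_permutations)) {
    acts <- m$activities
    acts[idx] <- acts[idx][perms[, b]]
    mb <- descriptor_matrix(m$compound_ids, m$descriptors, m$values, unname(acts))
    sel_b <- tryCatch(stepwise_forward_select(mb, train, recipe$max_descriptors),
                      error = function(e) NULL)
    if (is.null(sel_b)) next
    fit_b <- fit_pls(mb, train, sel_b, max_components = recipe$max_components)
    rec_b <- model_recipe(sel_b, n_components = fit_b$n_components,
                          max_descriptors = recipe$max_descriptors,
                          max_components = recipe$max_components)
    yb <- unname(mb$activities[idx])
    stats_mat[b, "r2"] <- fit_statistics(prediction_set(
      yb, predict(fit_b, mb$values[idx, sel_b, drop = FALSE])), k = length(sel_b))$r2
    stats_mat[b, "q2"] <- as.numeric(q_squared_loo(mb, train, q2_recipe(rec_b)))
    if (!is.null(h_pred))
      stats_mat[b, "pred_r2"] <- as.numeric(pred_r_squared(fit_b, mb, test))
  }
  summarize <- function(h, vals, name) {
    vals <- vals[is.finite(vals)]
    mu <- mean(vals); sigma <- stats::sd(vals)
    z <- if (sigma > 0) (h - mu) / sigma else {
      warning("zero spread in randomized ", name, "; Z reported as Inf")
      Inf
    }
    structure(list(statistic = name, h = h, mu = mu, sigma = sigma, z_score = z,
                   best = max(vals), p_value = (sum(vals >= h) + 1) / (length(vals) + 1),
                   n_permutations = n_permutations, seed = seed, values = vals),
              class = "randomization_result")
  }
  out <- list(r2 = summarize(h_r2, stats_mat[, "r2"], "r2"),
              q2 = summarize(h_q2, stats_mat[, "q2"], "q2"))
  if (!is.null(h_pred))
    out$pred_r2 <- summarize(h_pred, stats_mat[, "pred_r2"], "pred_r2")
  out
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf("<randomization %s: h = %.4f, mu = %.4f, sigma = %.4f, Z = %.4f (area %.2f%%), best = %.4f, p = %.4g>\n",
              x$statistic, x$h, x$mu, x$sigma, x$z_score,
              if (is.finite(x$z_score)) normal_area_percent(x$z_score) else 100,
              x$best, x$p_value))
  invisible(x)
}

#' Full validation report for a fitted model
#'
#' Computes the fit statistics on the training set, LOO q2, external
#' pred_r2 (if a test set is present), their standard errors, and (when
#' requested) the Y-randomization Z-scores with normal-curve areas.
#'
#' @param m descriptor_matrix.
#' @param split split_spec.
#' @param model qsar_model.
#' @param recipe model_recipe; defaults to the model's own descriptors and
#'   component count.
#' @param n_permutations permutations for Y-randomization; 0 skips it.
#' @param seed RNG seed for randomization.
#' @return object of class `validation_report` (a named list).
#' @export
validate_model <- function(m, split, model,
                           recipe = model_recipe(model$descriptor_names,
                                                 model$n_components),
                           n_permutations = 100L, seed = 42L) {
  tr <- training_matrix(m, split, model$descriptor_names)
  n <- nrow(tr$X); k <- length(model$descriptor_names)
  fs <- fit_statistics(prediction_set(tr$y, predict(model, tr$X)), k)
  q2 <- q_squared_loo(m, split, recipe)
  q2_se <- sqrt(sum((tr$y - attr(q2, "predictions"))^2) / fs$degrees_of_freedom)
  rep <- list(n = n, k = k, degrees_of_freedom = fs$degrees_of_freedom,
              n_components = model$n_components,
              r2 = fs$r2, r2_se = fs$se, f_test = fs$f_test,
              q2 = as.numeric(q2), q2_se = q2_se,
              pred_r2 = NA_real_, pred_r2_se = NA_real_)
  if (length(split$test_ids) > 0) {
    pr <- pred_r_squared(model, m, split)
    yhat <- attr(pr, "predictions")
    yte <- m$activities[split$test_ids]
    rep$pred_r2 <- as.numeric(pr)
    rep$pred_r2_se <- sqrt(sum((yte - yhat)^2) / max(length(yte) - 1, 1))
  }
  if (n_permutations > 0) {
    rnd <- y_randomization(m, split, recipe, n_permutations, seed,
                           test = if (length(split$test_ids) > 0) split)
    rep$randomization <- rnd
    rep$z_scores <- vapply(rnd, `[[`, numeric(1), "z_score")
    rep$normal_areas <- vapply(rep$z_scores, function(z)
      if (is.finite(z)) normal_area_percent(z) else 100, numeric(1))
  }
  structure(rep, class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation: n = %d, k = %d, df = %d, components = %d>\n",
              x$n, x$k, x$degrees_of_freedom, x$n_components))
  cat(sprintf("  r2 = %.4f (se %.4f)   q2 = %.4f (se %.4f)   F = %.4f\n",
              x$r2, x$r2_se, x$q2, x$q2_se, x$f_test))
  if (is.finite(x$pred_r2))
    cat(sprintf("  pred_r2 = %.4f (se %.4f)\n", x$pred_r2, x$pred_r2_se))
  if (!is.null(x$z_scores)) {
    cat("  Z-scores:", paste(sprintf("%s %.4f (%.2f%%)", names(x$z_scores),
                                     x$z_scores, x$normal_areas), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a validation report as JSON and a flat CSV
#'
#' The CSV mirrors the conventional randomization-table column names
#' (ZScore r2, ZScore q2, Best Rand r2, ...).
#'
#' @param report validation_report.
#' @param json_path,csv_path output files (NULL skips either).
#' @export
write_validation_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    j <- report[c("n", "k", "degrees_of_freedom", "n_components", "r2", "r2_se",
                  "f_test", "q2", "q2_se", "pred_r2", "pred_r2_se")]
    if (!is.null(report$randomization))
      j$randomization <- lapply(report$randomization, function(r)
        r[c("statistic", "h", "mu", "sigma", "z_score", "best", "p_value")])
    jsonlite::write_json(j, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  if (!is.null(csv_path) && !is.null(report$randomization)) {
    rnd <- report$randomization
    d <- data.frame(`Dep Variable` = "pIC50",
                    `ZScore r2` = rnd$r2$z_score,
                    `ZScore q2` = rnd$q2$z_score,
                    `Best Rand r2` = rnd$r2$best,
                    `Best Rand q2` = rnd$q2$best,
                    `Rand p r2` = rnd$r2$p_value,
                    `Rand p q2` = rnd$q2$p_value,
                    check.names = FALSE)
    if (!is.null(rnd$pred_r2)) {
      d$`Z Score Pred r2` <- rnd$pred_r2$z_score
      d$`best Rand Pred r2` <- rnd$pred_r2$best
      d$`Rand p Pred r2` <- rnd$pred_r2$p_value
    }
    utils::write.csv(d, csv_path, row.names = FALSE)
  }
  invisible(report)
}
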