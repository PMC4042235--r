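# Splitting, unicolumn statistics, stepwise-forward selection, PLS and the
# model equation.

random_dm <- function(n, p, seed, y = NULL) {
  set.seed(seed)
  vals <- matrix(rnorm(n * p), n)
  colnames(vals) <- paste0("S_", seq_len(p))
  if (is.null(y)) y <- rnorm(n)
  descriptor_matrix(sprintf("c%02d", seq_len(n)),
                    data.frame(name = colnames(vals), field_type = "steric",
                               index = seq_len(p), x = 0, y = 0, z = 0),
                    vals, y)
}

# exhaustive best-subset search scored by the same LOO criterion
brute_force_best <- function(X, y, k) {
  combos <- utils::combn(ncol(X), k, simplify = FALSE)
  scores <- vapply(combos, function(cb)
    fieldqsar:::loo_q2_ols(X[, cb, drop = FALSE], y), numeric(1))
  sort(combos[[which.max(scores)]])
}

test_that("unicolumn statistics are elementary and exact", {
  s <- unicolumn_stats(c(1, 2, 3))
  expect_equal(s[c("average", "max", "min", "std_dev", "sum")],
               list(average = 2, max = 3, min = 1, std_dev = 1, sum = 6))
  s1 <- unicolumn_stats(5)
  expect_equal(unlist(s1), c(average = 5, max = 5, min = 5, std_dev = 0, sum = 5))
  # the training-set extremes of a published thiosemicarbazone series
  s2 <- unicolumn_stats(c(5.31, 7.64))
  expect_equal(s2$average, 6.475)
  expect_equal(s2$max, 7.64)
  expect_equal(s2$min, 5.31)
  expect_error(unicolumn_stats(numeric(0)), "empty")
})

test_that("the interpolative split check applies strict inequalities", {
  # the published training/test extremes satisfy both conditions
  expect_true(check_split_interpolative(c(5.31, 6.1, 7.64), c(5.58, 7.099)))
  bad <- check_split_interpolative(c(1, 2), c(0, 1.5))
  expect_false(bad)
  expect_match(attr(bad, "messages"), "min")
  expect_false(check_split_interpolative(c(1, 2), c(1, 2)))  # boundary ties fail
})

test_that("stepwise-forward recovers planted columns and agrees with best-subset", {
  for (seed in 1:5) {
    pm <- planted_model(c("S_3", "S_7"), c(1.5, -1), 0, 0)
    m <- generate_descriptor_matrix(25, 50, pm, seed = seed)
    split <- split_spec(m$compound_ids)
    sel <- stepwise_forward_select(m, split, 2)
    expect_setequal(sel, c("S_3", "S_7"))
    bf <- brute_force_best(m$values, unname(m$activities), 2)
    expect_setequal(match(sel, colnames(m$values)), bf)
  }
})

test_that("stepwise selection caps, tie-breaks, and is deterministic", {
  pm <- planted_model(c("S_5", "S_9"), c(1, 1), 0, 0.05)
  m <- generate_descriptor_matrix(30, 30, pm, seed = 3)
  split <- split_spec(m$compound_ids)
  expect_lte(length(stepwise_forward_select(m, split, 4)), 4)
  # duplicated informative column: exactly one copy picked, the lower index
  m2 <- m
  m2$values[, "E_12"] <- m2$values[, "S_5"]
  sel2 <- stepwise_forward_select(m2, split, 3)
  expect_true("S_5" %in% sel2)
  expect_false("E_12" %in% sel2)
  expect_identical(stepwise_forward_select(m, split, 3),
                   stepwise_forward_select(m, split, 3))
  expect_error(stepwise_forward_select(m, split_spec(m$compound_ids[1:4]), 4),
               "training compounds")
})

test_that("PLS reduces to simple regression and to OLS at full rank", {
  m <- random_dm(15, 1, seed = 21, y = NULL)
  split <- split_spec(m$compound_ids)
  fit1 <- fit_pls(m, split, "S_1", 1)
  x <- m$values[, 1]; y <- unname(m$activities)
  expect_equal(unname(fit1$coefficients), cov(x, y) / var(x), tolerance = 1e-10)
  expect_equal(fit1$intercept, mean(y) - unname(fit1$coefficients) * mean(x),
               tolerance = 1e-10)
  # k components on a full-rank 20 x 5 problem equal the normal equations
  for (seed in 1:20) {
    m5 <- random_dm(20, 5, seed = 100 + seed)
    X <- m5$values; y <- unname(m5$activities)
    f <- fieldqsar:::pls_nipals(X, y, 5)
    ols <- solve(crossprod(cbind(1, X)), crossprod(cbind(1, X), y))
    pred_pls <- f$intercept + X %*% f$coef
    pred_ols <- cbind(1, X) %*% ols
    expect_equal(as.numeric(pred_pls), as.numeric(pred_ols), tolerance = 1e-8)
  }
})

test_that("PLS handles a constant response by returning the flat model", {
  m <- random_dm(10, 3, seed = 5, y = rep(4.2, 10))
  fit <- fit_pls(m, split_spec(m$compound_ids), c("S_1", "S_2"), 2)
  expect_equal(unname(fit$coefficients), c(0, 0))
  expect_equal(fit$intercept, 4.2)
})

test_that("prediction is the linear equation, errors name missing descriptors", {
  pub <- published_model()
  zero <- setNames(rep(0, 4), pub$descriptor_names)
  expect_identical(predict(pub, zero), 5.73211)
  e86 <- zero; e86["E_86"] <- 1
  expect_equal(predict(pub, e86), 9.63068, tolerance = 1e-12)
  v <- setNames(c(0.1, -0.2, 0.3, 4), pub$descriptor_names)
  expect_equal(predict(pub, 2 * v) - pub$intercept,
               2 * (predict(pub, v) - pub$intercept), tolerance = 1e-12)
  expect_error(predict(pub, v[-2]), "E_943")
})

test_that("contribution percentages are signed and sum to 100 in absolute value", {
  vals <- cbind(S_1 = c(0, 1, 2, 4), S_2 = c(1, 3, 0, 2))
  m <- descriptor_matrix(letters[1:4],
                         data.frame(name = colnames(vals), field_type = "steric",
                                    index = 1:2, x = 0, y = 0, z = 0),
                         vals, c(1, 2, 3, 4))
  one <- qsar_model("S_1", -2, 0)
  expect_equal(unname(contribution_percentages(one, m)), -100)
  # equal |coefficient x range|, opposite signs
  both <- qsar_model(c("S_1", "S_2"), c(1.5, -2), 0)  # ranges 4 and 3
  cp <- contribution_percentages(both, m)
  expect_equal(unname(cp), c(50, -50))
  expect_equal(sum(abs(cp)), 100, tolerance = 1e-9)
  # hand-computed products: 2*4 = 8 and 1*3 = 3
  cp2 <- contribution_percentages(qsar_model(c("S_1", "S_2"), c(2, 1), 0), m)
  expect_equal(unname(cp2), 100 * c(8, 3) / 11, tolerance = 1e-12)
  expect_error(contribution_percentages(qsar_model("S_1", 0, 1), m), "zero")
})

test_that("model JSON round trip preserves the equation", {
  tf <- tempfile(fileext = ".json")
  write_model_json(published_model(), tf)
  back <- read_model_json(tf)
  expect_equal(back$coefficients, published_model()$coefficients)
  expect_equal(back$intercept, 5.73211)
})
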