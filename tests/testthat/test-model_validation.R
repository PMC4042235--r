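# LOO q2, external pred_r2, fit statistics, Y-randomization and the normal
# curve area conversion.

planted_dm <- function(n = 24, p = 40, noise = 0, seed = 8) {
  generate_descriptor_matrix(n, p, planted_model(c("S_2", "E_20", "H_30"),
                                                 c(1, -0.7, 0.4), 6, noise),
                             seed = seed)
}

test_that("LOO q2 matches hand arithmetic on a worked 3-point example", {
  # actual (1,2,3), LOO predictions (1.1, 1.9, 3.2), mean 2:
  # q2 = 1 - 0.06/2 = 0.97
  y <- c(1, 2, 3); pred <- c(1.1, 1.9, 3.2)
  q2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  expect_equal(q2, 0.97, tolerance = 1e-12)
  # the implementation reproduces the identity on its own predictions
  m <- planted_dm()
  split <- split_spec(m$compound_ids)
  rec <- model_recipe(c("S_2", "E_20", "H_30"), 3)
  q2i <- q_squared_loo(m, split, rec)
  pr <- attr(q2i, "predictions")
  yy <- unname(m$activities)
  expect_equal(as.numeric(q2i),
               1 - sum((yy - pr)^2) / sum((yy - mean(yy))^2), tolerance = 1e-12)
  expect_equal(as.numeric(q2i), 1, tolerance = 1e-6)   # noiseless: perfect LOO
})

test_that("pred_r2 uses the training mean in its denominator", {
  desc <- data.frame(name = "S_1", field_type = "steric", index = 1,
                     x = 0, y = 0, z = 0)
  split <- split_spec(character(0), c("t1", "t2"))
  # identity model so the stored descriptor value IS the prediction;
  # hand example: y (6, 7), yhat (6.1, 6.8), ybar_train 6.5:
  # 1 - 0.05/0.5 = 0.9
  model_hand <- qsar_model("S_1", 1, 0, training_mean_activity = 6.5)
  mh <- descriptor_matrix(c("t1", "t2"), desc, cbind(S_1 = c(6.1, 6.8)),
                          c(6.0, 7.0))
  expect_equal(as.numeric(pred_r_squared(model_hand, mh, split)), 0.9,
               tolerance = 1e-12)
  # predictions equal to the training mean give exactly zero
  mzero <- descriptor_matrix(c("t1", "t2"), desc,
                             cbind(S_1 = c(6.5, 6.5)), c(6.0, 7.0))
  expect_equal(as.numeric(pred_r_squared(model_hand, mzero, split)), 0,
               tolerance = 1e-12)
  # perfect predictions give exactly one
  mperf <- descriptor_matrix(c("t1", "t2"), desc,
                             cbind(S_1 = c(6.0, 7.0)), c(6.0, 7.0))
  expect_equal(as.numeric(pred_r_squared(model_hand, mperf, split)), 1,
               tolerance = 1e-12)
})

test_that("pred_r2 is invariant to a common constant shift", {
  m <- planted_dm(noise = 0.1)
  split <- split_spec(m$compound_ids[1:19], m$compound_ids[20:24])
  sel <- c("S_2", "E_20", "H_30")
  model <- fit_pls(m, split, sel, 3)
  p1 <- as.numeric(pred_r_squared(model, m, split))
  m2 <- m; m2$activities <- m2$activities + 3
  model2 <- model
  model2$intercept <- model2$intercept + 3
  model2$training_mean_activity <- model2$training_mean_activity + 3
  expect_equal(as.numeric(pred_r_squared(model2, m2, split)), p1,
               tolerance = 1e-10)
})

test_that("fit statistics follow the F-test decomposition", {
  # n = 6, k = 1, SST = 10, SSE = 2: r2 = 0.8, F = 8 / (2/4) = 16
  y <- c(0, 2, 4, 6, 8, 10); y <- sqrt(10) * (y - mean(y)) / sqrt(sum((y - mean(y))^2)) + 5
  e <- c(1, -1, 1, -1, 1, -1) * sqrt(2 / 6)
  fs <- fit_statistics(prediction_set(y, y - e), k = 1)
  expect_equal(fs$r2, 0.8, tolerance = 1e-12)
  expect_equal(fs$f_test, 16, tolerance = 1e-12)
  expect_equal(fs$degrees_of_freedom, 4)
  expect_equal(fs$se, sqrt(2 / 4), tolerance = 1e-12)
  perfect <- fit_statistics(prediction_set(y, y), k = 1)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$se, 0)
  expect_true(is.infinite(perfect$f_test))
  flat <- fit_statistics(prediction_set(y, rep(mean(y), 6)), k = 1)
  expect_equal(flat$r2, 0)
  expect_equal(flat$f_test, 0)
  expect_error(fit_statistics(prediction_set(y[1:2], y[1:2]), k = 1), "n > k")
})

test_that("normal-curve areas reproduce the printed Z-score conversions", {
  expect_equal(normal_area_percent(0), 50.00)
  expect_equal(normal_area_percent(5.55599), 100.00)
  expect_equal(normal_area_percent(3.71813), 99.99)
  # 100 * pnorm(1.45442) = 92.7097; the upstream print truncates to 92.70
  expect_equal(normal_area_percent(1.45442), 92.71)
  z0 <- 1.37
  expect_equal(normal_area_percent(-z0), 100 - normal_area_percent(z0))
})

test_that("the Z-score is (h - mu) / sigma on the randomized distribution", {
  # arithmetic scale check: h 0.7232, mu 0.1, sigma 0.1676 -> Z about 3.718
  expect_equal((0.7232 - 0.1) / 0.1676, 3.71838, tolerance = 1e-4)
  m <- planted_dm(n = 20, p = 30, noise = 0.15, seed = 12)
  split <- split_spec(m$compound_ids)
  sel <- stepwise_forward_select(m, split, 3)
  rec <- model_recipe(sel, 3, max_descriptors = 3)
  rnd <- y_randomization(m, split, rec, n_permutations = 20, seed = 5)
  r <- rnd$q2
  expect_equal(r$z_score, (r$h - r$mu) / r$sigma, tolerance = 1e-12)
  expect_equal(r$best, max(r$values))
  expect_true(r$p_value > 0 && r$p_value <= 1)
  # determinism under the same seed
  rnd2 <- y_randomization(m, split, rec, n_permutations = 20, seed = 5)
  expect_equal(rnd2$q2$values, r$values)
  expect_equal(rnd2$r2$z_score, rnd$r2$z_score)
})

test_that("q2 on pure-noise activities stays low in expectation", {
  qs <- vapply(1:6, function(s) {
    m <- generate_descriptor_matrix(20, 15, planted_model("S_1", 0, 0, 1),
                                    seed = 200 + s)
    split <- split_spec(m$compound_ids)
    sel <- stepwise_forward_select(m, split, 2)
    as.numeric(q_squared_loo(m, split, model_recipe(sel, length(sel),
                                                    max_descriptors = 2)))
  }, numeric(1))
  expect_lt(mean(qs), 0.2)
  expect_true(all(qs <= 1))
})

test_that("the validation report assembles all statistics coherently", {
  m <- planted_dm(noise = 0.1, seed = 31)
  split <- split_spec(m$compound_ids[1:19], m$compound_ids[20:24])
  sel <- stepwise_forward_select(m, split, 3)
  model <- fit_pls(m, split, sel, 3)
  rep <- validate_model(m, split, model, n_permutations = 15, seed = 3)
  expect_equal(rep$n, 19)
  expect_equal(rep$k, length(sel))
  expect_true(rep$r2 <= 1 && rep$q2 <= 1 && rep$pred_r2 <= 1)
  expect_true(rep$r2_se >= 0 && rep$q2_se >= 0)
  expect_length(rep$z_scores, 3)
  tf <- tempfile(fileext = ".json"); tc <- tempfile(fileext = ".csv")
  write_validation_report(rep, tf, tc)
  expect_true(jsonlite::read_json(tf)$n == 19)
  csv <- read.csv(tc, check.names = FALSE)
  expect_true(all(c("ZScore r2", "ZScore q2", "Best Rand q2") %in% names(csv)))
})
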