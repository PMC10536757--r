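test_that("standardization is the z-score with explicit, portable stats", {
  st <- standardization_stats(data.frame(v = c(2, 4, 6)))
  z <- standardize(data.frame(v = c(2, 4, 6)), st)
  expect_equal(mean(z$v), 0)
  expect_equal(sd(z$v), 1)
  expect_error(standardization_stats(data.frame(k = rep(5, 4))), "k")
  # training-derived stats applied to test data need not re-centre it
  test_vals <- data.frame(v = c(10, 11, 12, 13, 14))
  zt <- standardize(test_vals, st)
  expect_equal(zt$v, (test_vals$v - 4) / 2)
  expect_gt(mean(zt$v), 0)
})

test_that("RMSE, MAE and R2 match hand-computed values", {
  m <- regression_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(m), c(rmse = 0, r2 = 1, mae = 0))
  m2 <- regression_metrics(c(1, 2, 3), c(2, 2, 2))
  expect_equal(m2$rmse, sqrt(2 / 3))
  expect_equal(m2$mae, 2 / 3)
  expect_equal(m2$r2, 0)     # constant observations: degenerate correlation
  # RMSE^2 = MSE; MAE <= RMSE; R2 invariant to positive affine transforms
  set.seed(17)
  for (i in 1:1000) {
    p <- rnorm(7); o <- rnorm(7)
    mm <- regression_metrics(p, o)
    expect_equal(mm$rmse^2, mean((p - o)^2))
    expect_lte(mm$mae, mm$rmse + 1e-12)
  }
  p <- rnorm(50); o <- p + rnorm(50)
  expect_equal(regression_metrics(2.5 * p + 1, o)$r2,
               regression_metrics(p, o)$r2)
})

test_that("cross-validation recovers a realizable linear target exactly", {
  set.seed(4)
  X <- data.frame(a = rnorm(60), b = rnorm(60))
  y <- 3 + 2 * X$a - X$b
  fit <- fit_cv(X, y, "linear", seed = 10)
  expect_lt(fit$cv_rmse, 1e-8)
  expect_gt(fit$cv_r2, 1 - 1e-8)
  expect_lt(fit$cv_mae, 1e-8)
})

test_that("cross-validation is deterministic given the seed", {
  set.seed(8)
  X <- data.frame(a = rnorm(40), b = rnorm(40))
  y <- X$a + rnorm(40)
  for (fam in c("linear", "gbt", "svm")) {
    f1 <- fit_cv(X, y, fam, seed = 99)
    f2 <- fit_cv(X, y, fam, seed = 99)
    expect_identical(f1$fold_assignments, f2$fold_assignments)
    expect_identical(f1$oof_pred, f2$oof_pred)
    expect_identical(f1[c("cv_rmse", "cv_r2", "cv_mae", "hyper")],
                     f2[c("cv_rmse", "cv_r2", "cv_mae", "hyper")])
    expect_true(is.finite(f1$cv_rmse) && f1$cv_rmse >= 0)
    expect_true(f1$cv_r2 >= 0 && f1$cv_r2 <= 1)
  }
  f3 <- fit_cv(X, y, "linear", seed = 100)
  expect_false(identical(f1$fold_assignments, f3$fold_assignments))
})

test_that("fit_cv validates its inputs", {
  expect_error(fit_cv(data.frame(a = 1:3), 1:3, "linear", seed = 1), "folds")
  X <- data.frame(a = c(1, 2, NA, 4, 5, 6))
  expect_error(fit_cv(X, rnorm(6), "linear", seed = 1), "finite")
  expect_error(fit_cv(data.frame(a = rnorm(10)), rnorm(10), "linear"), "seed")
})

test_that("transfer evaluation applies training stats and measures calibration", {
  set.seed(23)
  X <- data.frame(a = rnorm(80))
  y <- 2 * X$a + rnorm(80, sd = 0.2)
  fit <- fit_cv(X, y, "linear", seed = 3)
  # identical city: test metrics equal resubstitution metrics
  tr <- evaluate_transfer(fit, X, y, target_stats_policy = "training")
  resub <- regression_metrics(predict(fit, X),
                              standardize(data.frame(.target = y),
                                          fit$target_stats)[[1]])
  expect_equal(tr$test_rmse, resub$rmse)
  expect_equal(tr$test_r2, resub$r2)
  expect_lt(abs(tr$calibration_gap), 0.05)   # well-calibrated on itself
  # shifting the target by +0.5 training SD shifts the gap by -0.5
  y_shift <- y + 0.5 * sd(y)
  tr2 <- evaluate_transfer(fit, X, y_shift, target_stats_policy = "training")
  expect_equal(tr2$calibration_gap, tr$calibration_gap - 0.5 * sd(y) / fit$target_stats$sd,
               tolerance = 1e-8)
  expect_lt(abs(tr2$calibration_gap + 0.5), 0.06)
  # per-city standardization absorbs a pure location shift
  tr3 <- evaluate_transfer(fit, X, y_shift, target_stats_policy = "per_city")
  expect_lt(abs(tr3$calibration_gap), 0.05)
  expect_error(evaluate_transfer(fit, data.frame(zz = rnorm(80)), y), "columns")
})

test_that("confusion summaries compute sensitivity and specificity", {
  segs <- sprintf("s%02d", 1:30)
  truth <- data.frame(segment_id = segs,
                      sidewalk_truth = c(rep(TRUE, 10), rep(FALSE, 20)))
  perfect <- data.frame(segment_id = segs,
                        sidewalk_pred = truth$sidewalk_truth)
  cs <- sidewalk_accuracy(perfect, truth)
  expect_equal(cs$sensitivity, 1)
  expect_equal(cs$specificity, 1)
  # the tp=9 fn=1 tn=13 fp=7 operating point
  pred <- truth$sidewalk_truth
  pred[10] <- FALSE                 # one miss
  pred[11:17] <- TRUE               # seven false alarms
  cs2 <- sidewalk_accuracy(data.frame(segment_id = segs, sidewalk_pred = pred),
                           truth)
  expect_equal(c(cs2$tp, cs2$fn, cs2$tn, cs2$fp), c(9, 1, 13, 7))
  expect_equal(cs2$sensitivity, 0.90)
  expect_equal(cs2$specificity, 0.65)
  # all-positive predictor
  allp <- data.frame(segment_id = segs, sidewalk_pred = TRUE)
  cs3 <- sidewalk_accuracy(allp, truth)
  expect_equal(cs3$sensitivity, 1)
  expect_equal(cs3$specificity, 0)
  expect_error(sidewalk_accuracy(perfect[-1, ], truth), "differ")
})

test_that("the 1-SE rule prefers the smallest radius under flat performance", {
  # isolated intersections each with exactly one nearby point: radii 50 and
  # 100 capture identical data, so the curve is flat by construction
  k <- 12
  ints <- data.frame(id = sprintf("i%02d", 1:k),
                     x = seq(0, by = 1000, length.out = k), y = 0)
  pts <- data.frame(point_id = sprintf("p%02d", 1:k), segment_id = "s",
                    offset_m = 1, x = ints$x + 10, y = 0, excluded = FALSE)
  set.seed(31)
  sm <- do.call(rbind, lapply(1:k, function(i)
    make_summary_row(pts$point_id[i], 0, list(person = runif(1, 0, 0.2)))))
  truth <- data.frame(id = ints$id, value = sm$person + rnorm(k, sd = 0.01))
  sw <- sweep_buffers(ints, pts, sm, truth, feature_cols = "person",
                      radii = c(50, 100), families = "linear", k = 3, seed = 2)
  expect_equal(sw$results$cv_rmse[sw$results$buffer_m == 50],
               sw$results$cv_rmse[sw$results$buffer_m == 100])
  expect_equal(sw$selected_buffer_m, 50)
})

test_that("model objects print, predict and expose coefficients", {
  set.seed(12)
  X <- data.frame(a = rnorm(30))
  y <- 1 + X$a + rnorm(30, sd = 0.1)
  fit <- fit_cv(X, y, "linear", seed = 5, target_name = "trees")
  expect_output(print(fit), "trees")
  expect_output(summary(fit), "per-fold")
  expect_length(predict(fit, X), 30)
  expect_length(coef(fit), 2)
  expect_length(residuals(fit), 30)
  gfit <- fit_cv(X, y, "gbt", seed = 5)
  expect_error(coef(gfit), "linear")
})
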