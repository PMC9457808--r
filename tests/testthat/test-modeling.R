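# OLS fitting, validation statistics, train/test splitting, leverage and
# the frozen published model.

test_that("noiseless linear data is recovered exactly", {
  d <- gen_linear_dataset(sim_config(60, 6, noise_sd = 0, seed = 4))
  fit <- suppressWarnings(qstr_fit(d$table, d$y))
  expect_equal(unname(coef(fit)), unname(coef(d$model)), tolerance = 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit$q2_loo, 1, tolerance = 1e-10)
})

test_that("a constant response yields zero slopes and R2 = 0", {
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  fit <- suppressWarnings(qstr_fit(X, rep(2.5, 20)))
  expect_equal(unname(coef(fit)[-1]), rep(0, 3), tolerance = 1e-10)
  expect_equal(fit$r2, 0)
})

test_that("rank deficiency is an error naming the collinear column", {
  X <- cbind(a = rnorm(30), b = rnorm(30))
  X <- cbind(X, c = X[, "a"] * 2)
  expect_error(qstr_fit(X, rnorm(30)), "collinear.*c")
})

test_that("coefficient estimates cover the truth at the study size", {
  # planted beta, n/p as in the study regime; ~95% of estimates within 3 SE
  hits <- 0; total <- 0
  for (rep in 1:200) {
    d <- gen_linear_dataset(sim_config(152, 10, noise_sd = 0.5, seed = 1000 + rep))
    fit <- qstr_fit(d$table, d$y)
    truth <- coef(d$model)
    within <- abs(coef(fit) - truth) <= 3 * fit$se
    hits <- hits + sum(within); total <- total + length(within)
  }
  expect_gte(hits / total, 0.95)
})

test_that("standardized coefficients obey the sd ratio identity", {
  d <- gen_linear_dataset(sim_config(80, 5, noise_sd = 0.4, seed = 9))
  X <- as.matrix(d$table[, -1])
  fit <- qstr_fit(X, d$y)
  psd <- function(v) sd(v) * sqrt((length(v) - 1) / length(v))
  manual <- coef(fit)[-1] * apply(X, 2, psd) / psd(d$y)
  expect_equal(unname(fit$std_coeffs), unname(manual), tolerance = 1e-9)
  fit2 <- qstr_fit(X, d$y, sd_type = "sample")
  manual2 <- coef(fit2)[-1] * apply(X, 2, sd) / sd(d$y)
  expect_equal(unname(fit2$std_coeffs), unname(manual2), tolerance = 1e-9)
})

test_that("hat-matrix LOO equals the explicit refit loop and never beats R2", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(25:40, 1); p <- sample(3:5, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- X %*% rnorm(p) + rnorm(n, sd = runif(1, 0.2, 2))
    q_short <- q2_loo(X, y)
    q_refit <- q2_loo(X, y, method = "refit")
    expect_equal(q_short, q_refit, tolerance = 1e-10)
    r2 <- qstr_fit(X, y)$r2
    expect_lte(q_short, r2 + 1e-9)
  }
})

test_that("five-fold CV is exact on noiseless data and seed-sensitive on noisy data", {
  d0 <- gen_linear_dataset(sim_config(60, 4, noise_sd = 0, seed = 5))
  cv0 <- kfold_cv(d0$table, d0$y, seed = 99)
  expect_equal(cv0$mean_r2, 1, tolerance = 1e-10)
  expect_equal(cv0$mean_rmse, 0, tolerance = 1e-8)
  expect_equal(cv0$mean_mae, 0, tolerance = 1e-8)

  d <- gen_linear_dataset(sim_config(80, 6, noise_sd = 0.8, seed = 6))
  cv1 <- kfold_cv(d$table, d$y, seed = 1)
  cv2 <- kfold_cv(d$table, d$y, seed = 2)
  expect_false(isTRUE(all.equal(cv1$mean_r2, cv2$mean_r2)))
  expect_equal(kfold_cv(d$table, d$y, seed = 1)$mean_r2, cv1$mean_r2)  # determinism

  cvm <- kfold_cv(d$table, d$y, seed = 3, fold_mode = "median_r2")
  expect_equal(cvm$fold_mode, "median_r2")
  expect_length(cvm$r2, 5)
})

test_that("train/test split uses the floor rule consistent with h* = 0.217", {
  s <- split_train_test(sprintf("c%03d", 1:178), seed = 3)
  expect_length(s$test_ids, 26)
  expect_length(s$train_ids, 152)
  expect_equal(critical_leverage(10, length(s$train_ids)), 0.217, tolerance = 5e-4)

  expect_length(split_train_test(1:20, seed = 1)$test_ids, 3)
  s1 <- split_train_test(1:50, seed = 8); s2 <- split_train_test(1:50, seed = 8)
  expect_identical(s1, s2)
  expect_length(intersect(s1$train_ids, s1$test_ids), 0)
  expect_error(split_train_test(1:5), "at least 7")
})

test_that("leverage has the closed two-parameter form and unit trace identity", {
  X <- matrix(c(-1, 0, 1), ncol = 1)
  expect_equal(leverage(X), c(5/6, 1/3, 5/6), tolerance = 1e-12)
  set.seed(13)
  for (rep in 1:10) {
    n <- sample(20:60, 1); p <- sample(2:8, 1)
    Xr <- matrix(rnorm(n * p), n, p)
    h <- leverage(Xr)
    expect_equal(sum(h), p + 1, tolerance = 1e-9)
    expect_true(all(h > 0 & h <= 1))
  }
})

test_that("critical leverage reproduces the published cutoff and is decreasing in n", {
  expect_equal(round(critical_leverage(10, 152), 3), 0.217)
  expect_equal(critical_leverage(1, 30), 0.2)
  ns <- seq(30, 300, 10)
  expect_true(all(diff(critical_leverage(5, ns)) < 0))
})

test_that("Williams data flags leverage and residual outliers", {
  d <- gen_linear_dataset(sim_config(80, 5, noise_sd = 0.5, seed = 12))
  fit <- qstr_fit(d$table, d$y)
  wd <- williams_data(fit, ids = d$table$id)
  expect_true(all(is.finite(wd$std_residual)))
  expect_equal(attr(wd, "h_star"), critical_leverage(5, 80))
  expect_equal(wd$outlier, abs(wd$std_residual) > 3)

  far <- d$table[1, ]
  far[, -1] <- far[, -1] + 100          # far outside the descriptor ranges
  wd2 <- williams_data(fit, newdata = far, newy = d$y[1], ids = d$table$id)
  expect_false(wd2$in_domain[nrow(wd2)])
  expect_equal(sum(wd2$set == "Test"), 1)
})

test_that("the frozen published model reproduces its hand-computed dot products", {
  t1 <- reference_carbamate_rows()
  expect_equal(length(PUBLISHED_MODEL$names), 10)
  pred <- predict(PUBLISHED_MODEL, t1)
  expect_equal(pred[t1$id == "0000126523"], -0.6265, tolerance = 1e-3)
  expect_equal(pred[t1$id == "0006988201"], 0.3116, tolerance = 1e-3)
  zero <- as.data.frame(as.list(setNames(rep(0, 10), PUBLISHED_MODEL$names)))
  expect_equal(predict(PUBLISHED_MODEL, zero), 18.7033)
  expect_error(predict(PUBLISHED_MODEL, zero[, -3]), "LOC")
  # plausible-error guard against sign or column-order bugs
  expect_lte(sqrt(mean((pred - t1$log_inv_c)^2)), 0.60)
})

test_that("model specifications survive a JSON round trip", {
  path <- tempfile(fileext = ".json")
  write_qstr_model(PUBLISHED_MODEL, path)
  back <- read_qstr_model(path)
  expect_equal(coef(back), coef(PUBLISHED_MODEL))
})

test_that("prefilter drops constants and the weaker member of correlated pairs", {
  set.seed(30)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  y <- X[, "a"] + rnorm(50, sd = 0.1)
  Xd <- cbind(X, a_dup = X[, "a"], konst = 1)
  f <- prefilter(Xd, y)
  expect_false("konst" %in% colnames(f))
  expect_true(xor("a" %in% colnames(f), "a_dup" %in% colnames(f)))
  expect_equal(ncol(f), 4)

  t1 <- reference_carbamate_rows()
  f1 <- prefilter(t1, t1$log_inv_c, corr_threshold = 0.90)
  rem <- attr(f1, "removed")
  expect_equal(rem$column, "B05_CN")            # constant in every printed row
  expect_equal(rem$reason, "constant column")
  survivors <- setdiff(names(f1), c("id", "set", "log_inv_c"))
  expect_setequal(survivors, setdiff(PUBLISHED_MODEL$names, "B05_CN"))

  expect_error(prefilter(matrix(1, 10, 2), rnorm(10)), "all descriptor columns")
})
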