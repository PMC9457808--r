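# QSTR model core: frozen published model, OLS fitting via QR, internal
# validation (R2, leave-one-out Q2, k-fold CV) and the leverage-based
# applicability domain.

#' Frozen linear QSTR model specification
#'
#' @param names descriptor names, unique, same length as `coeffs`.
#' @param coeffs regression coefficients.
#' @param intercept intercept term.
#' @return object of class `"qstr_model"`.
#' @export
qstr_model <- function(names, coeffs, intercept) {
  names <- as.character(names)
  stopifnot(length(names) == length(coeffs), !anyDuplicated(names),
            is.numeric(coeffs), length(intercept) == 1, is.finite(intercept))
  structure(list(names = names, coeffs = stats::setNames(as.numeric(coeffs), names),
                 intercept = as.numeric(intercept)),
            class = "qstr_model")
}

#' The published ten-descriptor carbamate toxicity model
#'
#' Multi-linear model of log(1/C) (oral rat toxicity, C in mmol/kg) on the
#' two electronic descriptors EA and qC and eight structural descriptors,
#' with the reported coefficients frozen exactly.
#'
#' @format A [qstr_model()] with 10 coefficients and an intercept.
#' @export
PUBLISHED_MODEL <- qstr_model(
  names = c("EA", "qC", "LOC", "SpPosA_RG", "H4m", "nCt", "nROCON",
            "B05_CN", "B05_NO", "DLS_05"),
  coeffs = c(0.3231, -34.0837, -0.6319, -22.6053, -1.5012, 0.2275,
             -0.6919, 0.6524, 0.3996, 0.6244),
  intercept = 18.7033
)

#' @export
print.qstr_model <- function(x, ...) {
  cat("Linear QSTR model: log(1/C) =", format(x$intercept), "+\n")
  for (nm in x$names)
    cat(sprintf("  %+10.4f * %s\n", x$coeffs[[nm]], nm))
  invisible(x)
}

#' @export
coef.qstr_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coeffs)
}

#' Predict log(1/C) from a frozen model specification
#'
#' @param object a [qstr_model()].
#' @param newdata data frame (or named vector) supplying every descriptor
#'   named in the model; missing descriptors or missing values are errors.
#' @param ... unused.
#' @return numeric vector of predicted log(1/C).
#' @export
predict.qstr_model <- function(object, newdata, ...) {
  if (is.numeric(newdata) && !is.null(names(newdata)))
    newdata <- as.data.frame(as.list(newdata))
  absent <- setdiff(object$names, names(newdata))
  if (length(absent))
    stop("missing descriptor(s): ", paste(absent, collapse = ", "))
  X <- as.matrix(newdata[, object$names, drop = FALSE])
  if (anyNA(X)) {
    bad <- object$names[apply(is.na(X), 2, any)]
    stop("missing values in descriptor(s): ", paste(bad, collapse = ", "))
  }
  drop(object$intercept + X %*% object$coeffs)
}

#' Serialize / restore a model specification as JSON
#'
#' @param object a [qstr_model()].
#' @param path file path.
#' @return `read_qstr_model` returns a [qstr_model()].
#' @export
write_qstr_model <- function(object, path) {
  jsonlite::write_json(list(names = object$names,
                            coeffs = unname(object$coeffs),
                            intercept = object$intercept),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_qstr_model
#' @export
read_qstr_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  qstr_model(j$names, j$coeffs, j$intercept)
}

# Extract the numeric design matrix from a descriptor table or matrix.
.design_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
    return(x)
  }
  drop_cols <- intersect(c("id", "set", "log_inv_c"), names(x))
  keep <- setdiff(names(x), drop_cols)
  as.matrix(as.data.frame(x)[, keep, drop = FALSE])
}

#' Fit a multi-linear QSTR model
#'
#' Ordinary least squares through the QR factorization (via [stats::lm()]),
#' with the validation statistics of the trade: determination coefficient
#' R2, leave-one-out Q2 (hat-matrix shortcut), RMSE = sqrt(SSE/n), MAE,
#' standardized coefficients, 95% confidence half-widths and two-sided
#' t-test p-values.
#'
#' @param x descriptor table (data frame; columns `id`, `set`, `log_inv_c`
#'   are ignored as predictors) or numeric matrix, or a formula.
#' @param y numeric response, log(1/C); for the formula method taken from
#'   `data`.
#' @param ... further arguments passed to methods.
#' @return object of class `"qstr_fit"`; see [summary.qstr_fit()].
#' @examples
#' d <- gen_linear_dataset(sim_config(n_compounds = 60, n_descriptors = 5,
#'                                    noise_sd = 0.3, seed = 1))
#' fit <- qstr_fit(d$table, d$y)
#' summary(fit)
#' @export
qstr_fit <- function(x, ...) UseMethod("qstr_fit")

#' @rdname qstr_fit
#' @param data data frame for the formula method.
#' @export
qstr_fit.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  qstr_fit.default(X, y, ...)
}

#' @rdname qstr_fit
#' @param sd_type `"population"` (n denominator, default) or `"sample"`
#'   standard deviations for standardized coefficients.
#' @export
qstr_fit.default <- function(x, y, sd_type = c("population", "sample"), ...) {
  sd_type <- match.arg(sd_type)
  X <- .design_matrix(x)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) != nrow(x)")
  if (anyNA(X) || anyNA(y)) stop("missing values in fitting data; drop incomplete rows first")
  if (n <= p + 1) stop(sprintf("need n > p + 1 rows (n = %d, p = %d)", n, p))
  df <- data.frame(.y = y, X, check.names = FALSE)
  lmfit <- stats::lm(.y ~ ., data = df)
  if (lmfit$rank < p + 1) {
    aliased <- names(which(is.na(stats::coef(lmfit))))
    stop("rank-deficient design; collinear column(s): ",
         paste(aliased, collapse = ", "))
  }
  cf <- stats::coef(lmfit)
  res <- stats::residuals(lmfit)
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse / sst else 0  # constant response carries no signal
  h <- stats::lm.influence(lmfit, do.coef = FALSE)$hat
  if (any(h >= 1 - 1e-12)) stop("leverage of 1 encountered; LOO residual undefined")
  press <- sum((res / (1 - h))^2)
  q2 <- if (sst > 0) 1 - press / sst else 0
  sm <- summary(lmfit)
  se <- sm$coefficients[, "Std. Error"]
  pv <- sm$coefficients[, "Pr(>|t|)"]
  tcrit <- stats::qt(0.975, df = n - p - 1)
  sdfun <- function(v) {
    s <- stats::sd(v)
    if (sd_type == "population") s * sqrt((length(v) - 1) / length(v)) else s
  }
  std <- if (sst > 0)
    vapply(seq_len(p), function(j) cf[j + 1] * sdfun(X[, j]) / sdfun(y), 1)
  else rep(0, p)
  spec <- qstr_model(colnames(X), unname(cf[-1]), unname(cf[1]))
  structure(list(
    spec = spec,
    coefficients = cf,
    std_coeffs = stats::setNames(std, colnames(X)),
    conf_int95 = stats::setNames(tcrit * se, names(cf)),
    p_values = pv,
    se = se,
    r2 = r2, q2_loo = q2,
    rmse = sqrt(sse / n), mae = mean(abs(res)),
    sigma = sm$sigma,
    n_train = n, p = p,
    leverage = h,
    fitted = stats::fitted(lmfit),
    residuals = res,
    X = X, y = y
  ), class = "qstr_fit")
}

#' @export
print.qstr_fit <- function(x, ...) {
  cat(sprintf("QSTR linear model: n = %d, p = %d\n", x$n_train, x$p))
  cat(sprintf("  R2 = %.4f   Q2_LOO = %.4f   RMSE = %.4f   MAE = %.4f\n",
              x$r2, x$q2_loo, x$rmse, x$mae))
  invisible(x)
}

#' Summary of a fitted QSTR model
#'
#' @param object a `"qstr_fit"`.
#' @param ... unused.
#' @return the object, invisibly; prints coefficients, standardized
#'   coefficients, 95% confidence half-widths, p-values and the validation
#'   statistics, flagging Q2_LOO > 0.5 as acceptable.
#' @export
summary.qstr_fit <- function(object, ...) {
  tab <- data.frame(
    Coeff = object$coefficients,
    `Std.Coeff` = c(NA, object$std_coeffs),
    `Co.Int` = object$conf_int95,
    `p.value` = object$p_values,
    check.names = FALSE
  )
  print(format(tab, digits = 4))
  cat(sprintf("\nR2 = %.4f, Q2_LOO = %.4f (R2 - Q2 = %.4f), RMSE = %.4f, MAE = %.4f, n = %d\n",
              object$r2, object$q2_loo, object$r2 - object$q2_loo,
              object$rmse, object$mae, object$n_train))
  cat(if (object$q2_loo > 0.5)
    "Q2_LOO > 0.5: model internally predictive (acceptable).\n"
    else "Q2_LOO <= 0.5: model not internally predictive.\n")
  invisible(object)
}

#' @export
coef.qstr_fit <- function(object, ...) object$coefficients

#' @export
residuals.qstr_fit <- function(object, ...) object$residuals

#' @export
fitted.qstr_fit <- function(object, ...) object$fitted

#' @export
predict.qstr_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  predict(object$spec, newdata)
}

#' @export
simulate.qstr_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n_train
  out <- as.data.frame(replicate(nsim, object$fitted + stats::rnorm(n, 0, object$sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Leave-one-out cross-validated Q2
#'
#' \eqn{Q^2 = 1 - \sum_i (y_i - \hat y_{(-i)})^2 / \sum_i (y_i - \bar y)^2}
#' with the full-sample mean in the denominator.  The default computes LOO
#' residuals by the hat-matrix shortcut \eqn{e_i / (1 - h_{ii})};
#' `method = "refit"` performs the explicit n-fold refit loop (identical to
#' numerical precision, kept as an independent route).
#'
#' @param x design (descriptor table or matrix).
#' @param y response.
#' @param method `"shortcut"` or `"refit"`.
#' @return scalar Q2.
#' @export
q2_loo <- function(x, y, method = c("shortcut", "refit")) {
  method <- match.arg(method)
  X <- .design_matrix(x)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n <= ncol(X) + 2) stop("need n > p + 2 for leave-one-out validation")
  sst <- sum((y - mean(y))^2)
  if (method == "shortcut") {
    X1 <- cbind(1, X)
    qx <- qr(X1)
    if (qx$rank < ncol(X1)) stop("rank-deficient design")
    h <- rowSums(qr.Q(qx)^2)
    if (any(h >= 1 - 1e-12)) stop("leverage of 1 encountered; LOO residual undefined")
    res <- y - X1 %*% qr.coef(qx, y)
    press <- sum((res / (1 - h))^2)
  } else {
    press <- 0
    for (i in seq_len(n)) {
      Xi <- cbind(1, X[-i, , drop = FALSE])
      b <- qr.coef(qr(Xi), y[-i])
      pred <- sum(c(1, X[i, ]) * b)
      press <- press + (y[i] - pred)^2
    }
  }
  1 - press / sst
}

#' k-fold cross-validation of the linear model
#'
#' Rows are shuffled by `seed` and split into k near-equal folds; each fold
#' is scored by a model fitted on the remaining folds.  Out-of-fold R2 uses
#' the held-out fold's own response mean.  `fold_mode = "median_r2"`
#' generates 25 candidate fold assignments and keeps the one whose mean CV
#' R2 is the median, a deterministic "typical split" selection.
#'
#' @param x design (descriptor table or matrix).
#' @param y response.
#' @param k number of folds (default 5).
#' @param seed RNG seed.
#' @param fold_mode `"random"` (default) or `"median_r2"`.
#' @return list with per-fold `r2`, `rmse`, `mae` and their means
#'   `mean_r2`, `mean_rmse`, `mean_mae`.
#' @export
kfold_cv <- function(x, y, k = 5, seed = 1, fold_mode = c("random", "median_r2")) {
  fold_mode <- match.arg(fold_mode)
  X <- .design_matrix(x)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 2 * k) stop("need n >= 2k rows")
  one_cv <- function(fold_of) {
    r2 <- rmse <- mae <- numeric(k)
    for (f in seq_len(k)) {
      tr <- fold_of != f
      if (sum(tr) < ncol(X) + 2) stop("fold with too few training rows")
      Xtr <- cbind(1, X[tr, , drop = FALSE])
      b <- qr.coef(qr(Xtr), y[tr])
      if (anyNA(b)) stop("rank-deficient training fold")
      pred <- drop(cbind(1, X[!tr, , drop = FALSE]) %*% b)
      obs <- y[!tr]
      r2[f] <- 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
      rmse[f] <- sqrt(mean((obs - pred)^2))
      mae[f] <- mean(abs(obs - pred))
    }
    list(r2 = r2, rmse = rmse, mae = mae)
  }
  make_folds <- function() sample(rep(seq_len(k), length.out = n))
  set.seed(seed)
  if (fold_mode == "random") {
    res <- one_cv(make_folds())
  } else {
    cands <- replicate(25, make_folds(), simplify = FALSE)
    scores <- vapply(cands, function(fo) mean(one_cv(fo)$r2), 1)
    pick <- order(scores)[ceiling(length(scores) / 2)]
    res <- one_cv(cands[[pick]])
  }
  c(res, list(mean_r2 = mean(res$r2), mean_rmse = mean(res$rmse),
              mean_mae = mean(res$mae), k = k, fold_mode = fold_mode))
}

#' Split compound ids into training and test sets
#'
#' Draws `floor(test_fraction * n)` ids uniformly without replacement as the
#' test set (for 178 compounds at 15% this yields 26 test / 152 training
#' rows, the split consistent with the published critical leverage 0.217).
#'
#' @param ids vector of compound ids.
#' @param test_fraction fraction held out (default 0.15).
#' @param seed RNG seed.
#' @return list with `train_ids`, `test_ids`, `seed`.
#' @export
split_train_test <- function(ids, test_fraction = 0.15, seed = 1) {
  n <- length(ids)
  if (n < 7) stop("need at least 7 compounds to split")
  n_test <- floor(test_fraction * n)
  set.seed(seed)
  test <- sample(ids, n_test)
  list(train_ids = setdiff(ids, test), test_ids = test, seed = seed)
}

#' Leverage (hat) values of a training design
#'
#' \eqn{h_i = x_i' (X'X)^{-1} x_i} with an intercept column prepended,
#' computed from the thin QR factorization.  The leverages sum to p + 1.
#'
#' @param x training design (descriptor table or matrix), without intercept
#'   column.
#' @return numeric vector of leverages in (0, 1].
#' @export
leverage <- function(x) {
  X1 <- cbind(1, .design_matrix(x))
  qx <- qr(X1)
  if (qx$rank < ncol(X1)) stop("rank-deficient design")
  rowSums(qr.Q(qx)^2)
}

#' Critical leverage of the applicability domain
#'
#' \eqn{h^* = 3 (p + 1) / n}: descriptor count p = 10 and training size
#' n = 152 give the published cutoff 0.217.
#'
#' @param p number of descriptors in the model.
#' @param n number of training compounds.
#' @return scalar h*.
#' @export
critical_leverage <- function(p, n) {
  stopifnot(p >= 1, n > p + 1)
  3 * (p + 1) / n
}

#' Williams plot data: leverage vs standardized residuals
#'
#' For the training set (and optionally new compounds projected with the
#' training \eqn{(X'X)^{-1}}), tabulates leverage, standardized residual
#' (residual / training RMSE), the applicability-domain flag
#' `in_domain = (h <= h*)` and the response-outlier flag
#' `|std residual| > 3`.
#'
#' @param fit a `"qstr_fit"`.
#' @param newdata optional descriptor table of additional compounds.
#' @param newy optional observed responses for `newdata` (else residuals NA).
#' @param ids optional id labels for the training rows.
#' @return data frame of class `"williams_data"` with columns `id`, `set`,
#'   `leverage`, `std_residual`, `in_domain`, `outlier`; attribute
#'   `"h_star"`.
#' @export
williams_data <- function(fit, newdata = NULL, newy = NULL, ids = NULL) {
  stopifnot(inherits(fit, "qstr_fit"))
  h_star <- critical_leverage(fit$p, fit$n_train)
  if (is.null(ids)) ids <- paste0("train_", seq_len(fit$n_train))
  out <- data.frame(id = as.character(ids), set = "Training",
                    leverage = fit$leverage,
                    std_residual = fit$residuals / fit$rmse,
                    stringsAsFactors = FALSE)
  if (!is.null(newdata)) {
    Xn <- .design_matrix(newdata)[, colnames(fit$X), drop = FALSE]
    R <- qr.R(qr(cbind(1, fit$X)))
    # h_new = || R^-T x ||^2 via triangular solve
    Xn1 <- cbind(1, Xn)
    hn <- colSums(backsolve(R, t(Xn1), transpose = TRUE)^2)
    resn <- if (!is.null(newy)) (as.numeric(newy) - predict(fit$spec, as.data.frame(Xn))) / fit$rmse
            else NA_real_
    nid <- if (!is.null(newdata$id)) as.character(newdata$id)
           else paste0("new_", seq_len(nrow(Xn)))
    out <- rbind(out, data.frame(id = nid, set = "Test", leverage = hn,
                                 std_residual = resn, stringsAsFactors = FALSE))
  }
  out$in_domain <- out$leverage <= h_star
  out$outlier <- !is.na(out$std_residual) & abs(out$std_residual) > 3
  attr(out, "h_star") <- h_star
  class(out) <- c("williams_data", "data.frame")
  out
}

#' Williams plot of a fitted QSTR model
#'
#' Standardized residuals against leverage, with the +/- 3 sigma band and
#' the critical leverage h* marked.
#'
#' @param x a `"qstr_fit"`.
#' @param newdata,newy optional test-set table and responses, as in
#'   [williams_data()].
#' @param ... passed to [graphics::plot()].
#' @method plot qstr_fit
#' @export
plot.qstr_fit <- function(x, newdata = NULL, newy = NULL, ...) {
  wd <- williams_data(x, newdata = newdata, newy = newy)
  h_star <- attr(wd, "h_star")
  cols <- ifelse(wd$set == "Training", "steelblue", "purple")
  graphics::plot(wd$leverage, wd$std_residual, col = cols, pch = 19,
                 xlab = "Leverage h", ylab = "Standardized residual",
                 xlim = range(0, wd$leverage, h_star * 1.2),
                 ylim = range(-3.5, 3.5, wd$std_residual, na.rm = TRUE), ...)
  graphics::abline(h = c(-3, 3), lty = 2)
  graphics::abline(v = h_star, lty = 3)
  graphics::legend("topright", legend = c("Training", "Test", "h*"),
                   col = c("steelblue", "purple", "black"),
                   pch = c(19, 19, NA), lty = c(NA, NA, 3), bty = "n")
  invisible(wd)
}
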