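# End-to-end orchestration: descriptor table -> pre-filter -> train/test
# split -> (optional GA selection) -> fit -> validation -> applicability
# domain, with every stage's artifact persisted under one output directory
# and a manifest capturing configuration, seed and input checksums.

#' Run the QSTR modelling pipeline
#'
#' Takes a descriptor table (data frame or CSV path in the canonical
#' layout: `id`, optional `set`, optional `log_inv_c`, descriptor columns),
#' pre-filters inter-correlated descriptors, splits compounds into training
#' and test sets, optionally runs genetic-algorithm subset selection, fits
#' the linear model on the training rows, validates it (leave-one-out Q2,
#' k-fold CV) and tabulates the leverage applicability domain.  All stage
#' outputs are written under `out_dir`; reruns with the same inputs and
#' seed reproduce identical artifacts.
#'
#' @param descriptors descriptor table or CSV path.
#' @param response numeric response vector, or `NULL` to use the table's
#'   `log_inv_c` column.
#' @param out_dir output directory.
#' @param seed RNG seed driving the split, CV folds and GA.
#' @param test_fraction held-out fraction (default 0.15).
#' @param corr_threshold pre-filter correlation threshold (default 0.90).
#' @param k CV folds (default 5).
#' @param ga `NULL` (fit all surviving descriptors) or a [ga_config()].
#' @param fold_mode passed to [kfold_cv()].
#' @return invisibly, a list with the fitted `"qstr_fit"`, the
#'   [williams_data()] table, CV results, the split and the manifest.
#' @export
qstr_pipeline <- function(descriptors, response = NULL, out_dir,
                          seed = 1, test_fraction = 0.15,
                          corr_threshold = 0.90, k = 5, ga = NULL,
                          fold_mode = "random") {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  input_path <- if (is.character(descriptors)) descriptors else NULL
  tab <- stage("load", {
    if (is.character(descriptors))
      utils::read.csv(descriptors, stringsAsFactors = FALSE,
                      colClasses = c(id = "character"))
    else as.data.frame(descriptors)
  })
  if (!"id" %in% names(tab)) tab$id <- sprintf("cmpd_%04d", seq_len(nrow(tab)))
  y <- stage("load", {
    if (!is.null(response)) as.numeric(response)
    else if ("log_inv_c" %in% names(tab)) tab$log_inv_c
    else stop("no response: supply `response` or a log_inv_c column")
  })
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  complete <- stats::complete.cases(tab[, setdiff(names(tab), c("set")), drop = FALSE]) &
    is.finite(y)
  if (any(!complete))
    message(sprintf("excluding %d row(s) with missing values", sum(!complete)))
  tab <- tab[complete, , drop = FALSE]; y <- y[complete]

  filt <- stage("prefilter", prefilter(tab, y, corr_threshold = corr_threshold))
  utils::write.csv(attr(filt, "removed"),
                   file.path(out_dir, "prefilter_removed.csv"), row.names = FALSE)

  split <- stage("split", split_train_test(tab$id, test_fraction = test_fraction,
                                           seed = seed))
  jsonlite::write_json(split, file.path(out_dir, "split.json"),
                       auto_unbox = TRUE, digits = NA)
  tr <- tab$id %in% split$train_ids

  desc_cols <- setdiff(names(filt), c("id", "set", "log_inv_c"))
  if (!is.null(ga)) {
    sel <- stage("ga_select", ga_select(filt[tr, , drop = FALSE], y[tr], ga))
    utils::write.csv(sel, file.path(out_dir, "ga_hall_of_fame.csv"),
                     row.names = FALSE)
    desc_cols <- attr(sel, "best")
  }

  fit <- stage("fit", qstr_fit(as.matrix(filt[tr, desc_cols, drop = FALSE]), y[tr]))
  write_qstr_model(fit$spec, file.path(out_dir, "model.json"))

  cv <- stage("validate", kfold_cv(as.matrix(filt[tr, desc_cols, drop = FALSE]),
                                   y[tr], k = k, seed = seed,
                                   fold_mode = fold_mode))
  report <- list(
    n_train = fit$n_train, n_test = sum(!tr), p = fit$p,
    descriptors = desc_cols,
    r2 = fit$r2, q2_loo = fit$q2_loo, r2_minus_q2 = fit$r2 - fit$q2_loo,
    rmse = fit$rmse, mae = fit$mae,
    q2_acceptable = fit$q2_loo > 0.5,
    cv = cv[c("mean_r2", "mean_rmse", "mean_mae", "k", "fold_mode")],
    h_star = critical_leverage(fit$p, fit$n_train)
  )
  jsonlite::write_json(report, file.path(out_dir, "fit_report.json"),
                       auto_unbox = TRUE, digits = NA)

  wd <- stage("applicability", williams_data(
    fit,
    newdata = if (any(!tr)) filt[!tr, c("id", desc_cols), drop = FALSE] else NULL,
    newy = if (any(!tr)) y[!tr] else NULL,
    ids = tab$id[tr]))
  utils::write.csv(wd, file.path(out_dir, "williams.csv"), row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("qstr")),
    seed = seed, test_fraction = test_fraction,
    corr_threshold = corr_threshold, k = k, fold_mode = fold_mode,
    ga = if (is.null(ga)) NULL else unclass(ga),
    n_input = length(complete), n_used = sum(complete),
    input_checksum = {
      used <- file.path(out_dir, "input_used.csv")
      utils::write.csv(cbind(tab, log_inv_c_used = y), used, row.names = FALSE)
      c(input = if (!is.null(input_path)) unname(tools::md5sum(input_path)) else NA,
        used = unname(tools::md5sum(used)))
    }
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(fit = fit, williams = wd, cv = cv, split = split,
                 report = report, manifest = manifest))
}
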