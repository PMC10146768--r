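#' Coefficient of determination, adjusted R-squared and RMSE
#'
#' @param y Observed responses.
#' @param y_hat Predictions of the same length.
#' @param p Number of model terms (excluding the intercept), used for the
#'   adjustment; `r2_adj` is `NA` unless `n > p + 1`.
#' @return Named numeric vector `c(r2, r2_adj, rmse)` with
#'   `r2 = 1 - SS_res/SS_tot` and `rmse = sqrt(mean((y - y_hat)^2))`.
#' @export
fit_statistics <- function(y, y_hat, p) {
  stopifnot(length(y) == length(y_hat), length(y) >= 2L)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("zero response variance; R^2 undefined")
  ss_res <- sum((y - y_hat)^2)
  n <- length(y)
  r2 <- 1 - ss_res / ss_tot
  r2_adj <- if (n > p + 1L) 1 - (1 - r2) * (n - 1) / (n - p - 1) else NA_real_
  c(r2 = r2, r2_adj = r2_adj, rmse = sqrt(ss_res / n))
}

#' Durbin-Watson statistic
#'
#' Serial-correlation diagnostic of regression residuals in their fitting
#' order: values near 2 indicate no first-order autocorrelation, with the
#' model conventionally considered acceptable for 1.5 < DW < 2.5.
#'
#' @param residuals Numeric vector, length >= 2, not all zero.
#' @return `sum(diff(residuals)^2) / sum(residuals^2)`, in \[0, 4\].
#' @export
durbin_watson <- function(residuals) {
  stopifnot(length(residuals) >= 2L)
  denom <- sum(residuals^2)
  if (denom == 0) stop("all residuals are zero; DW undefined")
  sum(diff(residuals)^2) / denom
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` is from regressing column `j`
#' on the remaining columns with an intercept. Values above 5-10 flag
#' multicollinearity. Perfect collinearity yields `Inf`, not an error.
#'
#' @param X Matrix or `descriptor_table` of the model's descriptor
#'   columns (>= 2 columns).
#' @return Named numeric vector of VIFs, one per column.
#' @export
vif <- function(X) {
  x <- as.matrix(X)
  if (ncol(x) < 2L) stop("vif needs at least 2 columns")
  vapply(seq_len(ncol(x)), function(j) {
    fit <- lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    keep <- !is.na(fit$coefficients)
    ss_tot <- sum((x[, j] - mean(x[, j]))^2)
    if (ss_tot == 0) return(Inf)
    r2 <- 1 - sum(fit$residuals^2) / ss_tot
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE) -> out
  setNames(out, colnames(x))
}

#' Cross-validated q-squared on the training set
#'
#' Computes `q2 = 1 - PRESS/SS_tot` where PRESS accumulates squared
#' out-of-fold prediction errors over the training rows and SS_tot is
#' taken about the training mean. Leave-one-out (the default) is
#' deterministic; k-fold uses a seeded random fold assignment.
#'
#' @param dataset A `modeling_dataset` (training partition used) or list
#'   with `table` and `response`.
#' @param terms Character vector of descriptor names defining the model.
#' @param scheme `"loo"` or `"kfold"`.
#' @param k Number of folds for `"kfold"`.
#' @param seed Fold-assignment seed for `"kfold"`.
#' @return The q2 value (<= 1; can be negative for uninformative models).
#' @export
q2_cross_validation <- function(dataset, terms, scheme = c("loo", "kfold"),
                                k = 5L, seed = 1L) {
  scheme <- match.arg(scheme)
  x <- unclass(dataset$table)
  y <- dataset$response
  if (!is.null(dataset$train_ids)) {
    x <- x[dataset$train_ids, , drop = FALSE]
    y <- y[dataset$train_ids]
  }
  x <- x[, terms, drop = FALSE]
  n <- length(y)
  if (n <= length(terms) + 2L) stop("training set too small for CV")
  folds <- if (scheme == "loo") seq_len(n) else
    withr_seed(seed, sample(rep_len(seq_len(k), n)))
  press <- 0
  for (f in unique(folds)) {
    out <- folds == f
    if (sum(!out) <= length(terms) + 2L) {
      stop("fold with fewer rows than terms + 2")
    }
    fit <- fit_ols(x[!out, , drop = FALSE], y[!out])
    pred <- if (length(terms)) {
      drop(x[out, , drop = FALSE] %*% fit$coefficients) + fit$intercept
    } else rep(fit$intercept, sum(out))
    press <- press + sum((y[out] - pred)^2)
  }
  1 - press / sum((y - mean(y))^2)
}

#' Origin-regression slopes for external validation (Roy's k and k')
#'
#' `k` is the slope of observed regressed on predicted through the
#' origin, `k' ` the converse. External predictions are conventionally
#' acceptable when both lie within \[0.85, 1.15\].
#'
#' @param y_obs Observed values.
#' @param y_pred Predicted values, same length.
#' @param bounds Length-2 acceptance interval (default `c(0.85, 1.15)`).
#' @return List `k`, `k_prime`, `pass` (logical), `bounds`.
#' @export
roy_slopes <- function(y_obs, y_pred, bounds = c(0.85, 1.15)) {
  stopifnot(length(y_obs) == length(y_pred), length(y_obs) >= 2L)
  if (sum(y_pred^2) == 0 || sum(y_obs^2) == 0) {
    stop("zero-norm input; slopes undefined")
  }
  k <- sum(y_obs * y_pred) / sum(y_pred^2)
  k_prime <- sum(y_obs * y_pred) / sum(y_obs^2)
  list(k = k, k_prime = k_prime,
       pass = k >= bounds[1L] && k <= bounds[2L] &&
         k_prime >= bounds[1L] && k_prime <= bounds[2L],
       bounds = bounds)
}

#' Fold-difference coverage between observed and predicted doses
#'
#' Fraction of chemicals whose predicted and observed RfD agree within a
#' multiplicative factor: `max(pred/obs, obs/pred) <= factor`,
#' boundary inclusive (equivalently `|log10 pred - log10 obs| <=
#' log10(factor)`).
#'
#' @param rfd_obs,rfd_pred Positive dose vectors of equal length.
#' @param factors Fold factors > 1 (default `c(5, 10)`).
#' @return Named numeric vector of coverage fractions, one per factor.
#' @export
fold_coverage <- function(rfd_obs, rfd_pred, factors = c(5, 10)) {
  stopifnot(length(rfd_obs) == length(rfd_pred))
  if (any(rfd_obs <= 0) || any(rfd_pred <= 0)) {
    stop("doses must be positive")
  }
  if (any(factors <= 1)) stop("factors must exceed 1")
  ratio <- abs(log10(rfd_pred) - log10(rfd_obs))
  setNames(vapply(factors, function(f) mean(ratio <= log10(f)), numeric(1)),
           as.character(factors))
}

#' Adjusted R-squared versus model size along the stepwise path
#'
#' Records the adjusted R-squared reached after each stepwise entry, the
#' curve conventionally inspected to choose a model size that avoids
#' overfitting (the plateau point).
#'
#' @inheritParams fit_stepwise
#' @return Data frame with columns `n_terms` and `r2_adj`, one row per
#'   entry step (empty for an intercept-only outcome).
#' @export
model_size_curve <- function(dataset, cfg = stepwise_config()) {
  sw <- fit_stepwise(dataset, cfg)
  entries <- sw$log[sw$log$action == "enter", , drop = FALSE]
  data.frame(n_terms = seq_len(nrow(entries)), r2_adj = entries$r2_adj)
}

#' Full validation report for a fitted model
#'
#' Computes the training/test R-squared, adjusted R-squared, RMSEP on the
#' test partition, Durbin-Watson, VIFs, cross-validated q2, Roy's k/k'
#' on the test set, and fold-difference coverage on the RfD scale.
#'
#' @param model An `mlr_model` fitted on the training partition.
#' @param dataset The `modeling_dataset` the model was fitted on.
#' @param cv_scheme,cv_k,cv_seed Passed to [q2_cross_validation()].
#' @param coverage_factors Fold factors for [fold_coverage()].
#' @return A `validation_report` list mirroring the statistics above.
#' @export
validate_model <- function(model, dataset, cv_scheme = "loo", cv_k = 5L,
                           cv_seed = 1L, coverage_factors = c(5, 10)) {
  terms <- names(model$coefficients)
  x <- unclass(dataset$table)
  y <- dataset$response
  tr <- dataset$train_ids; te <- dataset$test_ids
  pred_tr <- predict(model, x[tr, , drop = FALSE])
  pred_te <- predict(model, x[te, , drop = FALSE])
  st_tr <- fit_statistics(y[tr], pred_tr, length(terms))
  st_te <- fit_statistics(y[te], pred_te, length(terms))
  all_pred <- c(pred_tr, pred_te)
  all_obs <- c(y[tr], y[te])
  structure(list(
    n_terms = length(terms),
    r2_train = unname(st_tr["r2"]),
    r2_adj = unname(st_tr["r2_adj"]),
    rmse_train = unname(st_tr["rmse"]),
    r2_test = unname(st_te["r2"]),
    rmsep = unname(st_te["rmse"]),
    dw = durbin_watson(model$residuals),
    vif = if (length(terms) >= 2L) vif(x[tr, terms, drop = FALSE]) else
      setNames(rep(1, length(terms)), terms),
    q2 = q2_cross_validation(dataset, terms, cv_scheme, cv_k, cv_seed),
    roy = roy_slopes(y[te], pred_te),
    coverage = fold_coverage(10^(-all_obs), 10^(-all_pred),
                             coverage_factors)
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    paste0("validation_report (%d terms)\n",
           "  R2 train %.3f (adj %.3f)  R2 test %.3f  RMSEP %.3f\n",
           "  DW %.3f  q2 %.3f  k %.3f  k' %.3f (pass: %s)\n"),
    x$n_terms, x$r2_train, x$r2_adj, x$r2_test, x$rmsep, x$dw, x$q2,
    x$roy$k, x$roy$k_prime, x$roy$pass))
  cat("  coverage:", paste(sprintf("%sx: %.1f%%", names(x$coverage),
                                   100 * x$coverage), collapse = "  "), "\n")
  invisible(x)
}
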