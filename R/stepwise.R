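#' Stepwise regression configuration
#'
#' @param p_enter Partial-F p-value below which a candidate descriptor
#'   enters the model (default 0.05, the usual stepwise default).
#' @param p_remove p-value above which an included descriptor is removed
#'   (default 0.10). Must exceed `p_enter` so a freshly entered term is
#'   not cycled straight out.
#' @param max_terms Upper bound on the number of descriptors; `Inf`
#'   (default) leaves the search unbounded.
#' @return A `stepwise_config` list.
#' @export
stepwise_config <- function(p_enter = 0.05, p_remove = 0.10,
                            max_terms = Inf) {
  stopifnot(p_enter >= 0, p_enter < 1, p_remove > 0, p_remove < 1,
            p_enter < p_remove, max_terms >= 1)
  structure(list(p_enter = p_enter, p_remove = p_remove,
                 max_terms = max_terms), class = "stepwise_config")
}

#' Ordinary least squares fit on selected descriptors
#'
#' Fits `y ~ 1 + X` by QR decomposition and packages the result as an
#' `mlr_model` with per-coefficient t statistics.
#'
#' @param X Numeric matrix (or `descriptor_table`) of the selected
#'   descriptor columns; may have zero columns for an intercept-only fit.
#' @param y Numeric response vector (-log10 RfD scale).
#' @return An `mlr_model`: `intercept`, `coefficients` (named),
#'   `n_train`, `residuals`, `fitted`, `sigma2`, `t_values`, `p_values`.
#' @export
fit_ols <- function(X, y) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 1L) stop(sprintf("need n > p + 1 (n=%d, p=%d)", n, p))
  design <- cbind(`(Intercept)` = 1, X)
  fit <- lm.fit(design, y)
  if (fit$rank < ncol(design)) {
    bad <- colnames(design)[is.na(fit$coefficients)]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  beta <- fit$coefficients
  res <- as.numeric(fit$residuals)
  df_res <- n - p - 1L
  sigma2 <- sum(res^2) / df_res
  xtx_inv <- chol2inv(fit$qr$qr[seq_len(ncol(design)), , drop = FALSE])
  se <- sqrt(sigma2 * diag(xtx_inv))
  tv <- beta / se
  structure(list(
    intercept = unname(beta[1L]),
    coefficients = beta[-1L],
    n_train = n,
    residuals = res,
    fitted = as.numeric(fit$fitted.values),
    sigma2 = sigma2,
    df_residual = df_res,
    t_values = tv[-1L],
    p_values = 2 * pt(abs(tv[-1L]), df_res, lower.tail = FALSE)
  ), class = "mlr_model")
}

#' @export
print.mlr_model <- function(x, ...) {
  cat(sprintf("mlr_model: intercept %.4g + %d descriptor terms (n = %d)\n",
              x$intercept, length(x$coefficients), x$n_train))
  if (length(x$coefficients)) {
    print(round(x$coefficients, 4))
  }
  invisible(x)
}

# p-value of the partial F test (1 df) for adding `cand` to the columns
# `sel` of x; equals the squared-t test of the new coefficient.
partial_f_p <- function(x, y, sel, cand) {
  design <- cbind(1, x[, c(sel, cand), drop = FALSE])
  fit <- lm.fit(design, y)
  if (fit$rank < ncol(design)) return(c(p = 1, abs_t = 0))
  n <- length(y)
  df <- n - ncol(design)
  if (df <= 0L) return(c(p = 1, abs_t = 0))
  sigma2 <- sum(fit$residuals^2) / df
  xtx_inv <- chol2inv(fit$qr$qr[seq_len(ncol(design)), , drop = FALSE])
  tval <- fit$coefficients[ncol(design)] /
    sqrt(sigma2 * diag(xtx_inv)[ncol(design)])
  if (!is.finite(tval)) return(c(p = 1, abs_t = 0))
  c(p = 2 * pt(abs(tval), df, lower.tail = FALSE), abs_t = abs(tval))
}

#' Forward-backward stepwise multiple linear regression
#'
#' At each step the excluded descriptor with the smallest partial-F
#' p-value enters when `p < p_enter`; after every entry, included
#' descriptors with `p > p_remove` exit (worst first). Candidate ties are
#' broken by larger |t| and then column order. Terminates when no move is
#' possible; if nothing ever qualifies the result is an intercept-only
#' model with an empty log.
#'
#' @param dataset A `modeling_dataset` from [build_dataset()], or a list
#'   with `table` and `response`; fitting uses the training partition.
#' @param cfg A [stepwise_config()].
#' @return List with `model` (an `mlr_model` refit on the selected terms)
#'   and `log`, a data frame of every entry/exit (`step`, `action`,
#'   `descriptor`, `p_value`, `r2_adj`).
#' @export
fit_stepwise <- function(dataset, cfg = stepwise_config()) {
  x <- unclass(dataset$table)
  y <- dataset$response
  if (!is.null(dataset$train_ids)) {
    x <- x[dataset$train_ids, , drop = FALSE]
    y <- y[dataset$train_ids]
  }
  n <- length(y)
  nm <- colnames(x)
  sel <- integer()
  log_rows <- list()
  step <- 0L
  repeat {
    cand <- setdiff(seq_len(ncol(x)), sel)
    if (!length(cand) || length(sel) >= cfg$max_terms) break
    if (n - length(sel) - 2L <= 0L) break
    stats <- vapply(cand, function(j) partial_f_p(x, y, sel, j),
                    c(p = 0, abs_t = 0))
    ord <- order(stats["p", ], -stats["abs_t", ], cand)
    best <- ord[1L]
    if (stats["p", best] >= cfg$p_enter) break
    step <- step + 1L
    sel <- c(sel, cand[best])
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      step = step, action = "enter", descriptor = nm[cand[best]],
      p_value = stats["p", best],
      r2_adj = adj_r2_of(x, y, sel), stringsAsFactors = FALSE)
    # backward sweep
    repeat {
      if (length(sel) < 1L) break
      fit <- fit_ols(x[, sel, drop = FALSE], y)
      pv <- fit$p_values
      worst <- which.max(pv)
      if (pv[worst] <= cfg$p_remove) break
      step <- step + 1L
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        step = step, action = "remove", descriptor = nm[sel[worst]],
        p_value = unname(pv[worst]),
        r2_adj = adj_r2_of(x, y, sel[-worst]), stringsAsFactors = FALSE)
      sel <- sel[-worst]
    }
  }
  model <- fit_ols(x[, sel, drop = FALSE], y)
  list(model = model,
       log = if (length(log_rows)) do.call(rbind, log_rows) else
         data.frame(step = integer(), action = character(),
                    descriptor = character(), p_value = numeric(),
                    r2_adj = numeric(), stringsAsFactors = FALSE))
}

adj_r2_of <- function(x, y, sel) {
  if (!length(sel)) return(0)
  fit <- fit_ols(x[, sel, drop = FALSE], y)
  fit_statistics(y, fit$fitted, length(sel))["r2_adj"][[1L]]
}

#' Predict -log10(RfD) for one chemical
#'
#' @param model An `mlr_model`.
#' @param descriptors Named numeric vector (or single-row table) giving a
#'   value for every model term; missing terms are an error, never a
#'   silent zero.
#' @return The predicted -log10(RfD).
#' @export
predict_neg_log_rfd <- function(model, descriptors) {
  descriptors <- unlist(descriptors)
  need <- names(model$coefficients)
  missing <- setdiff(need, names(descriptors))
  if (length(missing)) {
    stop("missing descriptor value(s): ", paste(missing, collapse = ", "))
  }
  model$intercept + sum(model$coefficients * descriptors[need])
}

#' Predict -log10(RfD) for every row of a descriptor table
#'
#' @param object An `mlr_model`.
#' @param newdata A `descriptor_table` or matrix containing all model
#'   terms as columns.
#' @param ... Unused.
#' @return Named numeric vector of predictions.
#' @export
predict.mlr_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  need <- names(object$coefficients)
  missing <- setdiff(need, colnames(x))
  if (length(missing)) {
    stop("missing descriptor column(s): ", paste(missing, collapse = ", "))
  }
  if (length(need) == 0L) {
    return(setNames(rep(object$intercept, nrow(x)), rownames(x)))
  }
  drop(x[, need, drop = FALSE] %*% object$coefficients) + object$intercept
}

#' Convert -log10(RfD) back to an RfD
#'
#' @param y -log10(RfD) value(s).
#' @return `10^(-y)`, mg/kg/d.
#' @export
neg_log_to_rfd <- function(y) 10^(-y)

#' Round a reference dose to a number of significant figures
#'
#' Regulatory adoption conventionally keeps one significant figure
#' (e.g. a predicted 0.01271 mg/kg/d is adopted as 0.01).
#'
#' @param rfd Positive dose value(s).
#' @param sig_figs Number of significant figures, >= 1 (default 1).
#' @return Rounded value(s).
#' @export
adopt_rfd <- function(rfd, sig_figs = 1L) {
  if (sig_figs < 1L) stop("sig_figs must be >= 1")
  if (any(rfd <= 0)) stop("rfd must be positive")
  signif(rfd, sig_figs)
}

#' Serialize a fitted model to JSON
#'
#' @param model An `mlr_model`.
#' @param path Output path.
#' @param extra Optional named list merged into the JSON (e.g. step log,
#'   config).
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path, extra = list()) {
  payload <- c(list(
    intercept = model$intercept,
    coefficients = as.list(model$coefficients),
    n_train = model$n_train,
    t_values = as.list(model$t_values)
  ), extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a model from JSON written by [write_model_json()]
#'
#' @param path JSON path.
#' @return An `mlr_model` (prediction fields only).
#' @export
read_model_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(intercept = j$intercept,
                 coefficients = unlist(j$coefficients),
                 n_train = j$n_train %||% NA_integer_,
                 residuals = numeric(), fitted = numeric(),
                 t_values = unlist(j$t_values %||% list())),
            class = "mlr_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
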