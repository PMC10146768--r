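#' Descriptor screening configuration
#'
#' Thresholds for the three pre-processing rules applied before model
#' building: (1) drop zero-variance descriptors, (2) drop descriptors with
#' fewer than 10% non-zero values, (3) drop one of any pair with absolute
#' Pearson correlation above 0.90.
#'
#' @param variance_epsilon Columns with sample variance <= this are removed
#'   (default 0, i.e. exactly constant columns).
#' @param nonzero_fraction_min Minimum fraction of non-zero entries a
#'   column must have to survive; strict `<` comparison, so exactly the
#'   threshold fraction is retained. Default 0.10.
#' @param corr_threshold Absolute-correlation cut-off; pairs with
#'   `|r| > corr_threshold` lose one member. Default 0.90.
#' @param zero_tolerance Entries with `|x| <= zero_tolerance` count as
#'   zero (guards against float dust). Default 1e-12.
#' @return A `screening_config` list.
#' @export
screening_config <- function(variance_epsilon = 0,
                             nonzero_fraction_min = 0.10,
                             corr_threshold = 0.90,
                             zero_tolerance = 1e-12) {
  stopifnot(variance_epsilon >= 0,
            nonzero_fraction_min >= 0, nonzero_fraction_min <= 1,
            corr_threshold >= 0, corr_threshold <= 1,
            zero_tolerance >= 0)
  structure(list(variance_epsilon = variance_epsilon,
                 nonzero_fraction_min = nonzero_fraction_min,
                 corr_threshold = corr_threshold,
                 zero_tolerance = zero_tolerance),
            class = "screening_config")
}

empty_removals <- function() {
  data.frame(descriptor = character(), rule = character(),
             partner = character(), stringsAsFactors = FALSE)
}

subset_columns <- function(table, keep) {
  descriptor_table(unclass(table)[, keep, drop = FALSE],
                   chem_ids = rownames(table),
                   descriptor_names = colnames(table)[keep])
}

#' Remove zero-variance descriptors
#'
#' @param table A `descriptor_table`.
#' @param cfg A [screening_config()].
#' @return List with `table` (filtered) and `removed` (data frame with
#'   columns descriptor, rule, partner).
#' @export
filter_zero_variance <- function(table, cfg = screening_config()) {
  if (ncol(table) == 0L) return(list(table = table, removed = empty_removals()))
  v <- apply(unclass(table), 2L, var)
  drop <- which(v <= cfg$variance_epsilon)
  removed <- empty_removals()
  if (length(drop)) {
    removed <- data.frame(descriptor = colnames(table)[drop],
                          rule = "zero_variance", partner = NA_character_,
                          stringsAsFactors = FALSE)
  }
  list(table = subset_columns(table, setdiff(seq_len(ncol(table)), drop)),
       removed = removed)
}

#' Remove sparse descriptors
#'
#' A column is sparse when its fraction of non-zero entries (by
#' `zero_tolerance`) is strictly below `nonzero_fraction_min`.
#'
#' @inheritParams filter_zero_variance
#' @return List with `table` and `removed`.
#' @export
filter_sparse <- function(table, cfg = screening_config()) {
  if (ncol(table) == 0L) return(list(table = table, removed = empty_removals()))
  frac <- colMeans(abs(unclass(table)) > cfg$zero_tolerance)
  drop <- which(frac < cfg$nonzero_fraction_min)
  removed <- empty_removals()
  if (length(drop)) {
    removed <- data.frame(descriptor = colnames(table)[drop],
                          rule = "sparse", partner = NA_character_,
                          stringsAsFactors = FALSE)
  }
  list(table = subset_columns(table, setdiff(seq_len(ncol(table)), drop)),
       removed = removed)
}

#' Remove one member of each highly correlated descriptor pair
#'
#' Pairs are scanned greedily in column order; when
#' `|r| > corr_threshold`, the victim is the member with the smaller
#' absolute correlation to the response (when supplied), otherwise the
#' member with the larger mean absolute correlation to all other columns;
#' ties drop the lexicographically later name. Dropped columns are
#' excluded from later pairs.
#'
#' @inheritParams filter_zero_variance
#' @param response Optional numeric vector aligned to the table rows,
#'   used to prefer the more predictive member of a pair.
#' @return List with `table` and `removed`; each removal records the
#'   surviving `partner` that triggered it.
#' @export
filter_correlated <- function(table, cfg = screening_config(),
                              response = NULL) {
  p <- ncol(table)
  if (p < 2L) return(list(table = table, removed = empty_removals()))
  x <- unclass(table)
  if (any(apply(x, 2L, var) == 0)) {
    stop("constant column encountered; run filter_zero_variance first")
  }
  r <- cor(x)
  ry <- if (!is.null(response)) {
    stopifnot(length(response) == nrow(x))
    abs(cor(x, response)[, 1L])
  }
  nm <- colnames(x)
  alive <- rep(TRUE, p)
  removed <- list()
  mean_abs_r <- function(j) mean(abs(r[j, alive & seq_len(p) != j]))
  for (i in seq_len(p - 1L)) {
    if (!alive[i]) next
    for (j in seq.int(i + 1L, p)) {
      if (!alive[i]) break
      if (!alive[j]) next
      if (abs(r[i, j]) > cfg$corr_threshold) {
        victim <- if (!is.null(ry) && ry[i] != ry[j]) {
          if (ry[i] < ry[j]) i else j
        } else {
          mi <- mean_abs_r(i); mj <- mean_abs_r(j)
          if (mi > mj) i else if (mj > mi) j else max_name(i, j, nm)
        }
        survivor <- if (victim == i) j else i
        alive[victim] <- FALSE
        removed[[length(removed) + 1L]] <- data.frame(
          descriptor = nm[victim], rule = "correlated",
          partner = nm[survivor], stringsAsFactors = FALSE)
      }
    }
  }
  removed <- if (length(removed)) do.call(rbind, removed) else empty_removals()
  list(table = subset_columns(table, which(alive)), removed = removed)
}

# locale-independent (C collation) "later name" for tie-breaking
max_name <- function(i, j, nm) {
  if (sort(nm[c(i, j)], method = "radix")[2L] == nm[i]) i else j
}

#' Apply the full three-stage descriptor screen
#'
#' Runs the zero-variance, sparsity and correlation filters in that
#' order and assembles an auditable report. A column removable by two
#' rules is attributed to the earliest stage that fires.
#'
#' @inheritParams filter_correlated
#' @return List with `table` (screened `descriptor_table`) and `report`,
#'   a `screening_report` containing `removed` (descriptor, rule,
#'   partner), `retained` (ordered names) and `counts` (columns before
#'   and after each stage).
#' @export
screen_descriptors <- function(table, cfg = screening_config(),
                               response = NULL) {
  n0 <- ncol(table)
  s1 <- filter_zero_variance(table, cfg)
  s2 <- filter_sparse(s1$table, cfg)
  s3 <- filter_correlated(s2$table, cfg, response)
  removed <- rbind(s1$removed, s2$removed, s3$removed)
  report <- structure(list(
    removed = removed,
    retained = colnames(s3$table),
    counts = data.frame(
      stage = c("input", "zero_variance", "sparse", "correlated"),
      n_descriptors = c(n0, ncol(s1$table), ncol(s2$table), ncol(s3$table))
    )
  ), class = "screening_report")
  list(table = s3$table, report = report)
}

#' @export
print.screening_report <- function(x, ...) {
  cat("descriptor screening report\n")
  print(x$counts, row.names = FALSE)
  if (nrow(x$removed)) {
    cat("removals by rule:\n")
    print(table(x$removed$rule))
  }
  invisible(x)
}
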