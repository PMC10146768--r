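#' Specification of a synthetic QSAR dataset
#'
#' Describes a descriptor matrix with the structural features real
#' descriptor exports exhibit — correlated blocks, constant columns,
#' sparse columns, exact duplicates, count-valued columns — plus a
#' sparse linear ground truth for the -log10(RfD) response.
#'
#' Defaults encode the working conditions of the modelled study: 109
#' chemicals, residual noise 0.434 on the -log10 scale (the reported
#' prediction error), an intercept of 1.468, and a 3-term true support
#' with coefficients of the magnitude seen in the published equation.
#' The descriptor count defaults to 50 (a computationally tractable
#' stand-in for the several-hundred-column tables real generators emit).
#'
#' @param n_chemicals Number of rows.
#' @param n_descriptors Total columns, including degenerate ones.
#' @param n_constant,n_sparse,n_duplicated Counts of constant columns,
#'   columns with < 10% non-zero entries, and exact duplicates of
#'   regular columns.
#' @param n_count Count-valued (non-negative integer) columns among the
#'   regular ones, mimicking atom-count descriptors.
#' @param true_support Names of the regular columns carrying signal.
#' @param true_coefficients Their coefficients, same length.
#' @param intercept Response intercept, -log10(mg/kg/d).
#' @param noise_sd Gaussian noise SD on the -log10 scale.
#' @param block_correlation Pairwise correlation within blocks of 5
#'   regular Gaussian columns, in \[0, 1).
#' @param seed Integer seed; every generator is a pure function of the
#'   spec including this seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_chemicals = 109L, n_descriptors = 50L,
                           n_constant = 3L, n_sparse = 4L,
                           n_duplicated = 5L, n_count = 5L,
                           true_support = c("X01", "X02", "X03"),
                           true_coefficients = c(1.0, -0.8, 0.6),
                           intercept = 1.468, noise_sd = 0.434,
                           block_correlation = 0.3, seed = 1L) {
  n_regular <- n_descriptors - n_constant - n_sparse - n_duplicated
  stopifnot(n_chemicals >= 3L, n_regular >= 1L,
            length(true_support) == length(true_coefficients),
            noise_sd >= 0, block_correlation >= 0, block_correlation < 1,
            n_count <= n_regular)
  spec <- structure(list(
    n_chemicals = as.integer(n_chemicals),
    n_descriptors = as.integer(n_descriptors),
    n_constant = as.integer(n_constant), n_sparse = as.integer(n_sparse),
    n_duplicated = as.integer(n_duplicated), n_count = as.integer(n_count),
    n_regular = as.integer(n_regular),
    true_support = true_support,
    true_coefficients = setNames(true_coefficients, true_support),
    intercept = intercept, noise_sd = noise_sd,
    block_correlation = block_correlation, seed = as.integer(seed)
  ), class = "synthetic_spec")
  if (!all(true_support %in% regular_names(spec))) {
    stop("true_support must name regular (non-degenerate) columns, e.g. ",
         paste(head(regular_names(spec), 3), collapse = ", "))
  }
  spec
}

regular_names <- function(spec) {
  sprintf("X%02d", seq_len(spec$n_regular))
}

#' Generate a synthetic descriptor table
#'
#' Regular columns are standard Gaussian within correlated blocks of 5
#' (single-factor structure with the requested pairwise correlation);
#' the last `n_count` regular columns are converted to non-negative
#' counts. Degenerate columns are appended: constants, sparse columns
#' with 5% non-zero entries, and exact duplicates of the first regular
#' columns. Deterministic for a fixed spec.
#'
#' @param spec A [synthetic_spec()].
#' @return A `descriptor_table` of dimension
#'   `n_chemicals x n_descriptors`.
#' @export
generate_descriptor_matrix <- function(spec) {
  withr_seed(spec$seed, {
    n <- spec$n_chemicals
    p <- spec$n_regular
    rho <- spec$block_correlation
    block <- 5L
    x <- matrix(rnorm(n * p), n, p)
    if (rho > 0) {
      for (b in seq_len(ceiling(p / block))) {
        cols <- seq.int((b - 1L) * block + 1L, min(b * block, p))
        z <- rnorm(n)
        x[, cols] <- sqrt(rho) * z + sqrt(1 - rho) * x[, cols]
      }
    }
    colnames(x) <- regular_names(spec)
    if (spec$n_count > 0L) {
      cc <- seq.int(p - spec$n_count + 1L, p)
      # counts with matching first two moments, like *_acnt descriptors
      x[, cc] <- matrix(rpois(n * spec$n_count, 2), n)
    }
    parts <- list(x)
    if (spec$n_constant > 0L) {
      const <- matrix(rep(runif(spec$n_constant, 1, 5), each = n), n)
      colnames(const) <- sprintf("const%02d", seq_len(spec$n_constant))
      parts <- c(parts, list(const))
    }
    if (spec$n_sparse > 0L) {
      k <- max(1L, floor(0.05 * n))
      sp <- matrix(0, n, spec$n_sparse)
      for (j in seq_len(spec$n_sparse)) {
        sp[sample.int(n, k), j] <- rnorm(k, sd = 2)
      }
      colnames(sp) <- sprintf("sparse%02d", seq_len(spec$n_sparse))
      parts <- c(parts, list(sp))
    }
    if (spec$n_duplicated > 0L) {
      # duplicate trailing regular columns so the signal-bearing leading
      # ones keep their own names through the correlation filter
      src <- rev(regular_names(spec))[seq_len(spec$n_duplicated)]
      dup <- x[, src, drop = FALSE]
      colnames(dup) <- paste0("dup_", src)
      parts <- c(parts, list(dup))
    }
    out <- do.call(cbind, parts)
    descriptor_table(out, chem_ids = sprintf("chem%03d", seq_len(n)),
                     descriptor_names = colnames(out))
  })
}

#' Generate responses from the synthetic linear ground truth
#'
#' `neg_log_rfd = intercept + X[, support] %*% beta + N(0, noise_sd^2)`,
#' converted back to an RfD as `10^(-neg_log_rfd)`. The noise stream is
#' seeded with `spec$seed + 1` so matrix and response draws do not alias.
#'
#' @param table A `descriptor_table` containing the support columns.
#' @param spec The [synthetic_spec()] used to build it.
#' @return Chemical records (see [chemical_records()]) aligned to the
#'   table rows.
#' @export
generate_response <- function(table, spec) {
  x <- unclass(table)
  stopifnot(all(spec$true_support %in% colnames(x)))
  signal <- if (length(spec$true_support)) {
    drop(x[, spec$true_support, drop = FALSE] %*% spec$true_coefficients)
  } else 0
  noise <- withr_seed(spec$seed + 1L,
                      rnorm(nrow(x), sd = spec$noise_sd))
  y <- spec$intercept + signal + noise
  chemical_records(rownames(x), 10^(-y))
}

#' Generate a lognormal monitoring-concentration table
#'
#' Site concentrations in ng/L drawn from a lognormal distribution. The
#' defaults place roughly 95% of a few hundred sites between about
#' 0.002 and 140 ng/L, the span reported for organochlorine pesticide
#' surveys.
#'
#' @param n_sites Number of sites, >= 1.
#' @param log_mean Mean of log concentration (natural log of ng/L).
#' @param log_sd SD of log concentration.
#' @param seed Integer seed.
#' @return Data frame with columns `site_id`, `eec_ng_per_L`.
#' @export
generate_monitoring_table <- function(n_sites, log_mean = -0.64,
                                      log_sd = 2.1, seed = 1L) {
  stopifnot(n_sites >= 1L, log_sd >= 0)
  eec <- withr_seed(seed, rlnorm(n_sites, log_mean, log_sd))
  data.frame(site_id = sprintf("site%03d", seq_len(n_sites)),
             eec_ng_per_L = eec, stringsAsFactors = FALSE)
}
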