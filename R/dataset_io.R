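#' Read a descriptor table from CSV
#'
#' The first column holds chemical identifiers (CAS numbers or names,
#' treated as opaque strings); every remaining column must be numeric and
#' fully observed. Row and column order are preserved.
#'
#' @param path Path to a CSV file with a header row.
#' @param check_names Passed to [utils::read.csv()]; default `FALSE` keeps
#'   descriptor names verbatim.
#' @return A `descriptor_table`: a numeric matrix (chemicals x descriptors)
#'   with `rownames` = chemical ids and `colnames` = descriptor names.
#' @export
load_descriptor_table <- function(path, check_names = FALSE) {
  if (!file.exists(path)) stop("descriptor file not found: ", path)
  df <- read.csv(path, check.names = check_names, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop("empty descriptor table: ", path)
  }
  ids <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1L]
      stop(sprintf("non-numeric value in column '%s', row %d",
                   names(vals)[j], if (is.na(bad)) 1L else bad))
    }
  }
  descriptor_table(as.matrix(vals), chem_ids = ids,
                   descriptor_names = colnames(vals))
}

#' Construct and validate a descriptor table
#'
#' @param values Numeric matrix, chemicals in rows, descriptors in columns.
#' @param chem_ids Character vector of unique chemical identifiers.
#' @param descriptor_names Character vector of unique descriptor names.
#' @return A validated `descriptor_table` matrix.
#' @export
descriptor_table <- function(values, chem_ids = rownames(values),
                             descriptor_names = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(chem_ids) || is.null(descriptor_names)) {
    stop("chem_ids and descriptor_names are required")
  }
  chem_ids <- as.character(chem_ids)
  descriptor_names <- as.character(descriptor_names)
  if (nrow(values) != length(chem_ids) || ncol(values) != length(descriptor_names)) {
    stop("matrix dimensions inconsistent with id/name lists")
  }
  dup <- chem_ids[duplicated(chem_ids)]
  if (length(dup)) stop("duplicate chemical identifier: ", dup[1L])
  dupn <- descriptor_names[duplicated(descriptor_names)]
  if (length(dupn)) stop("duplicate descriptor name: ", dupn[1L])
  if (anyNA(values) || any(!is.finite(values))) {
    idx <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at chemical '%s', descriptor '%s'",
                 chem_ids[idx[1L]], descriptor_names[idx[2L]]))
  }
  dimnames(values) <- list(chem_ids, descriptor_names)
  class(values) <- c("descriptor_table", class(values))
  values
}

#' Write a descriptor table to CSV
#'
#' Inverse of [load_descriptor_table()]; the identifier column is written
#' first under the name `chem_id`.
#'
#' @param table A `descriptor_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(table, path) {
  vals <- unclass(table)
  # %.17g keeps doubles bit-exact through the text round-trip
  body <- apply(vals, 1L, function(r) paste(sprintf("%.17g", r),
                                            collapse = ","))
  lines <- c(paste(c("chem_id", colnames(vals)), collapse = ","),
             paste(rownames(vals), body, sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a response table of reference doses
#'
#' Expects two columns: chemical identifier and RfD in mg/kg/d. The
#' -log10 transform is applied on load.
#'
#' @param path CSV path.
#' @return Data frame with columns `chem_id`, `rfd`, `neg_log_rfd`.
#' @export
load_response_table <- function(path) {
  if (!file.exists(path)) stop("response file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L || nrow(df) == 0L) stop("empty response table: ", path)
  chemical_records(as.character(df[[1L]]), as.numeric(df[[2L]]))
}

#' Build chemical records from identifiers and reference doses
#'
#' @param chem_id Character vector of identifiers.
#' @param rfd Positive reference doses, mg/kg/d.
#' @return Data frame with columns `chem_id`, `rfd`, `neg_log_rfd`
#'   (`= -log10(rfd)`).
#' @export
chemical_records <- function(chem_id, rfd) {
  chem_id <- as.character(chem_id)
  rfd <- as.numeric(rfd)
  if (length(chem_id) != length(rfd)) stop("length mismatch")
  dup <- chem_id[duplicated(chem_id)]
  if (length(dup)) stop("duplicate chemical identifier: ", dup[1L])
  bad <- which(!is.finite(rfd) | rfd <= 0)
  if (length(bad)) {
    stop("rfd must be positive and finite; offender: ", chem_id[bad[1L]])
  }
  data.frame(chem_id = chem_id, rfd = rfd, neg_log_rfd = -log10(rfd),
             stringsAsFactors = FALSE)
}

#' Join descriptors and responses into a modeling dataset
#'
#' Aligns responses to the descriptor table by identifier, computes the
#' -log10(RfD) response and draws a reproducible random train/test split.
#' The default training fraction, 80/109, yields the conventional 80/29
#' partition on a 109-chemical dataset.
#'
#' @param table A `descriptor_table`.
#' @param responses Data frame from [chemical_records()] (or any with
#'   `chem_id` and `rfd` columns).
#' @param train_fraction Fraction of chemicals assigned to the training
#'   set, in (0, 1).
#' @param seed Integer seed controlling the split; recorded in the result.
#' @return A `modeling_dataset` list: `table`, `response` (named numeric,
#'   -log10 RfD), `rfd`, `train_ids`, `test_ids`, `train_fraction`,
#'   `split_seed`.
#' @export
build_dataset <- function(table, responses, train_fraction = 80 / 109,
                          seed) {
  stopifnot(inherits(table, "descriptor_table"))
  if (missing(seed)) stop("seed is required for a reproducible split")
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop("train_fraction must lie in (0, 1)")
  }
  ids <- rownames(table)
  m <- match(ids, responses$chem_id)
  if (anyNA(m)) {
    stop("missing response for chemical: ", ids[which(is.na(m))[1L]])
  }
  rfd <- responses$rfd[m]
  if (any(rfd <= 0)) stop("rfd must be positive; offender: ",
                          ids[which(rfd <= 0)[1L]])
  y <- setNames(-log10(rfd), ids)
  n_train <- round(train_fraction * length(ids))
  n_train <- max(1L, min(length(ids) - 1L, n_train))
  train_ids <- withr_seed(seed, sample(ids, n_train))
  structure(list(
    table = table,
    response = y,
    rfd = setNames(rfd, ids),
    train_ids = sort(train_ids),
    test_ids = sort(setdiff(ids, train_ids)),
    train_fraction = train_fraction,
    split_seed = as.integer(seed)
  ), class = "modeling_dataset")
}

# Evaluate expr under a local RNG seed without disturbing the caller's
# random state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' @export
print.modeling_dataset <- function(x, ...) {
  cat(sprintf(
    "modeling_dataset: %d chemicals x %d descriptors (train %d / test %d, seed %d)\n",
    nrow(x$table), ncol(x$table), length(x$train_ids), length(x$test_ids),
    x$split_seed))
  invisible(x)
}
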