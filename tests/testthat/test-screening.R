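make_screen_fixture <- function(seed = 3, n = 100) {
  # 40 columns: 3 constant, 4 sparse, 5 exact duplicates, 28 regular
  set.seed(seed)
  x <- matrix(rnorm(n * 28), n, 28)
  colnames(x) <- sprintf("reg%02d", 1:28)
  const <- matrix(rep(c(3.7, 0, -2), each = n), n)
  colnames(const) <- sprintf("const%d", 1:3)
  sp <- matrix(0, n, 4)
  for (j in 1:4) sp[sample.int(n, 5), j] <- 1  # 5% non-zero
  colnames(sp) <- sprintf("sparse%d", 1:4)
  dup <- x[, 1:5]
  colnames(dup) <- sprintf("dup%d", 1:5)
  descriptor_table(cbind(x, const, sp, dup),
                   chem_ids = sprintf("c%03d", seq_len(n)),
                   descriptor_names = c(colnames(x), colnames(const),
                                        colnames(sp), colnames(dup)))
}

test_that("zero-variance filter removes exactly the constant columns", {
  tab <- descriptor_table(cbind(a = rep(3.7, 20), b = c(rep(0, 19), 1)),
                          chem_ids = sprintf("c%d", 1:20),
                          descriptor_names = c("a", "b"))
  res <- filter_zero_variance(tab)
  expect_identical(res$removed$descriptor, "a")
  expect_identical(colnames(res$table), "b")

  # random 100x50 with 7 injected constants; brute-force variance oracle
  set.seed(9)
  x <- matrix(rnorm(100 * 50), 100, 50)
  const_idx <- sample(50, 7)
  x[, const_idx] <- rep(runif(7), each = 100)
  nm <- sprintf("D%02d", 1:50)
  tab <- descriptor_table(x, sprintf("c%03d", 1:100), nm)
  res <- filter_zero_variance(tab)
  oracle <- nm[vapply(seq_len(50), function(j) var(x[, j]) == 0, logical(1))]
  expect_setequal(res$removed$descriptor, oracle)
  expect_setequal(res$removed$descriptor, nm[const_idx])
})

test_that("sparse filter uses a strict <10% boundary and counts correctly", {
  n <- 100
  mk <- function(k) c(rnorm(k), rep(0, n - k))
  tab <- descriptor_table(cbind(five = mk(5), ten = mk(10)),
                          chem_ids = sprintf("c%d", 1:n),
                          descriptor_names = c("five", "ten"))
  res <- filter_sparse(tab)
  expect_identical(res$removed$descriptor, "five")
  expect_identical(colnames(res$table), "ten")  # exactly 10% retained

  # random sparse matrix with known support sizes vs a counting oracle
  set.seed(21)
  supp <- sample(1:30, 12)
  x <- sapply(supp, function(k) sample(mk(k)))
  colnames(x) <- sprintf("S%02d", seq_along(supp))
  tab <- descriptor_table(x, sprintf("c%d", 1:n), colnames(x))
  res <- filter_sparse(tab)
  oracle <- colnames(x)[colSums(abs(x) > 1e-12) / n < 0.10]
  expect_setequal(res$removed$descriptor, oracle)
})

test_that("correlation filter enforces |r| <= threshold with partners", {
  set.seed(5)
  base <- rnorm(60)
  tab <- descriptor_table(cbind(a = base, b = base, c = rnorm(60)),
                          chem_ids = sprintf("c%d", 1:60),
                          descriptor_names = c("a", "b", "c"))
  res <- filter_correlated(tab)
  expect_identical(nrow(res$removed), 1L)
  expect_true(res$removed$descriptor %in% c("a", "b"))
  expect_true(res$removed$partner %in% c("a", "b"))

  # negative correlation counts through the absolute value
  v <- -base + rnorm(60, sd = 0.15)
  expect_lt(cor(base, v), -0.9)
  neg <- descriptor_table(cbind(u = base, v = v),
                          chem_ids = sprintf("c%d", 1:60),
                          descriptor_names = c("u", "v"))
  res <- filter_correlated(neg)
  expect_identical(nrow(res$removed), 1L)

  # exhaustive all-pairs oracle on a random correlated table
  set.seed(6)
  z <- matrix(rnorm(60 * 30), 60, 30)
  z[, 2] <- z[, 1] + rnorm(60, sd = 0.1)
  z[, 10] <- -z[, 9] + rnorm(60, sd = 0.05)
  tab <- descriptor_table(z, sprintf("c%d", 1:60), sprintf("D%02d", 1:30))
  res <- filter_correlated(tab)
  r <- cor(unclass(res$table))
  expect_lte(max(abs(r[upper.tri(r)])), 0.90)
})

test_that("response-guided removal keeps the more predictive member", {
  set.seed(8)
  good <- rnorm(80)
  y <- 2 * good + rnorm(80, sd = 0.1)
  bad <- good + rnorm(80, sd = 0.05)  # correlated with good, less with y
  stopifnot(abs(cor(good, bad)) > 0.9, abs(cor(good, y)) > abs(cor(bad, y)))
  tab <- descriptor_table(cbind(bad = bad, good = good),
                          chem_ids = sprintf("c%d", 1:80),
                          descriptor_names = c("bad", "good"))
  res <- filter_correlated(tab, response = y)
  expect_identical(res$removed$descriptor, "bad")
  expect_identical(res$removed$partner, "good")
})

test_that("the composed screen removes known columns with correct labels", {
  tab <- make_screen_fixture()
  scr <- screen_descriptors(tab)
  rem <- scr$report$removed
  expect_identical(nrow(rem), 12L)
  expect_setequal(rem$descriptor[rem$rule == "zero_variance"],
                  sprintf("const%d", 1:3))
  expect_setequal(rem$descriptor[rem$rule == "sparse"],
                  sprintf("sparse%d", 1:4))
  expect_identical(sum(rem$rule == "correlated"), 5L)
  # each duplicate pair loses exactly one member
  for (j in 1:5) {
    pair <- c(sprintf("reg%02d", j), sprintf("dup%d", j))
    expect_identical(sum(pair %in% scr$report$retained), 1L)
  }
  expect_setequal(c(rem$descriptor, scr$report$retained), colnames(tab))
  expect_identical(scr$report$counts$n_descriptors, c(40L, 37L, 33L, 28L))
})

test_that("screening is idempotent", {
  tab <- make_screen_fixture(seed = 13)
  once <- screen_descriptors(tab)
  twice <- screen_descriptors(once$table)
  expect_identical(unclass(twice$table), unclass(once$table))
  expect_identical(nrow(twice$report$removed), 0L)
})

test_that("correlation filter refuses constant columns", {
  tab <- descriptor_table(cbind(a = rep(1, 10), b = rnorm(10)),
                          chem_ids = sprintf("c%d", 1:10),
                          descriptor_names = c("a", "b"))
  expect_error(filter_correlated(tab), "constant")
})
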