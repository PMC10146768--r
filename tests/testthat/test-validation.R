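test_that("fit_statistics matches its definition", {
  set.seed(1)
  y <- rnorm(30)
  expect_equal(unname(fit_statistics(y, y, 3)[c("r2", "rmse")]), c(1, 0))
  expect_equal(unname(fit_statistics(y, rep(mean(y), 30), 3)["r2"]), 0)
  expect_error(fit_statistics(rep(1, 5), rnorm(5), 1), "variance")

  for (s in 1:20) {
    set.seed(s)
    y <- rnorm(30); yh <- rnorm(30); p <- sample(1:5, 1)
    st <- fit_statistics(y, yh, p)
    r2 <- 1 - sum((y - yh)^2) / sum((y - mean(y))^2)
    expect_equal(unname(st["r2"]), r2, tolerance = 1e-12)
    expect_equal(unname(st["r2_adj"]),
                 1 - (1 - r2) * 29 / (30 - p - 1), tolerance = 1e-12)
    expect_equal(unname(st["rmse"]), sqrt(mean((y - yh)^2)),
                 tolerance = 1e-12)
  }
})

test_that("durbin_watson matches hand values and the asymptotic null", {
  expect_equal(durbin_watson(c(1, -1, 1, -1)), 3)
  expect_equal(durbin_watson(c(1, 1, 1, 1)), 0)
  expect_error(durbin_watson(rep(0, 4)), "zero")
  set.seed(77)
  e <- rnorm(1e4)
  expect_lt(abs(durbin_watson(e) - 2), 0.1)
  for (s in 1:20) {
    set.seed(s); e <- rnorm(50)
    d <- durbin_watson(e)
    expect_gte(d, 0); expect_lte(d, 4)
  }
})

test_that("vif matches per-column auxiliary regressions", {
  # orthogonal centered columns -> exactly 1
  set.seed(33)
  q <- qr.Q(qr(scale(matrix(rnorm(100 * 4), 100, 4), scale = FALSE)))
  expect_equal(unname(vif(q)), rep(1, 4), tolerance = 1e-8)

  x <- matrix(rnorm(50 * 2), 50, 2)
  expect_identical(unname(vif(cbind(x, x[, 1]))[c(1, 3)]), c(Inf, Inf))

  for (s in 1:10) {
    set.seed(s)
    z <- matrix(rnorm(100 * 5), 100, 5)
    z[, 2] <- z[, 1] * 0.8 + z[, 2] * 0.3
    expect_equal(unname(vif(z)), oracle_vif(z), tolerance = 1e-8)
  }
})

test_that("q2 cross-validation equals the explicit refit loop", {
  # noiseless linear data -> q2 = 1
  set.seed(3)
  x <- matrix(rnorm(30 * 2), 30, 2, dimnames = list(NULL, c("a", "b")))
  y <- 1 + x[, 1] - 2 * x[, 2]
  ds <- list(table = x, response = y)
  expect_equal(q2_cross_validation(ds, c("a", "b")), 1, tolerance = 1e-10)

  # LOO equals brute force on a small dataset
  set.seed(4)
  x <- matrix(rnorm(10 * 2), 10, 2, dimnames = list(NULL, c("a", "b")))
  y <- x[, 1] + rnorm(10)
  expect_equal(q2_cross_validation(list(table = x, response = y),
                                   c("a", "b")),
               oracle_loo_q2(x, y), tolerance = 1e-10)

  # uninformative model -> typically negative; PRESS >= SS_res always
  q2s <- r2s <- numeric(50)
  for (s in 1:50) {
    set.seed(s)
    x <- matrix(rnorm(100 * 3), 100, 3,
                dimnames = list(NULL, c("a", "b", "c")))
    y <- rnorm(100)
    ds <- list(table = x, response = y)
    q2s[s] <- q2_cross_validation(ds, c("a", "b", "c"))
    fit <- fit_ols(x, y)
    r2s[s] <- fit_statistics(y, fit$fitted, 3)["r2"]
  }
  expect_lt(median(q2s), 0)
  expect_true(all(q2s <= r2s))  # PRESS >= SS_res

  expect_error(q2_cross_validation(list(table = x[1:4, ], response = y[1:4]),
                                   c("a", "b", "c")), "too small")
})

test_that("k-fold q2 is seeded and reproducible", {
  set.seed(10)
  x <- matrix(rnorm(60 * 2), 60, 2, dimnames = list(NULL, c("a", "b")))
  y <- x[, 1] + rnorm(60, sd = 0.5)
  ds <- list(table = x, response = y)
  a <- q2_cross_validation(ds, c("a", "b"), "kfold", k = 5, seed = 42)
  b <- q2_cross_validation(ds, c("a", "b"), "kfold", k = 5, seed = 42)
  expect_identical(a, b)
})

test_that("roy_slopes follow the origin-regression closed forms", {
  y <- c(1, 2, 3, 4.5)
  r <- roy_slopes(y, y)
  expect_equal(c(r$k, r$k_prime), c(1, 1))
  expect_true(r$pass)

  r <- roy_slopes(y, 2 * y)
  expect_equal(c(r$k, r$k_prime), c(0.5, 2))
  expect_false(r$pass)

  for (s in 1:10) {
    set.seed(s)
    obs <- rnorm(29, mean = 2); pred <- obs + rnorm(29, sd = 0.3)
    r <- roy_slopes(obs, pred)
    o <- oracle_roy(obs, pred)
    expect_equal(r$k, unname(o["k"]), tolerance = 1e-10)
    expect_equal(r$k_prime, unname(o["k_prime"]), tolerance = 1e-10)
    # scaling identities
    cc <- runif(1, 0.5, 3)
    rs <- roy_slopes(obs, cc * obs)
    expect_equal(rs$k, 1 / cc, tolerance = 1e-12)
    expect_equal(rs$k_prime, cc, tolerance = 1e-12)
  }
  expect_error(roy_slopes(c(0, 0), c(0, 0)), "zero-norm")
})

test_that("fold coverage is inclusive, monotone, and matches the
           analytic lognormal oracle", {
  obs <- 10^runif(20, -4, 0)
  expect_identical(unname(fold_coverage(obs, obs, c(2, 5, 10))),
                   c(1, 1, 1))
  expect_identical(unname(fold_coverage(1, 10, 10)), 1)   # boundary
  expect_identical(unname(fold_coverage(1, 10.5, 10)), 0)
  expect_error(fold_coverage(c(1, -1), c(1, 1), 10), "positive")

  set.seed(11)
  n <- 1e4
  sdlog <- log(10) / 4
  obs <- 10^runif(n, -5, -1)
  pred <- obs * rlnorm(n, 0, sdlog)
  cov <- fold_coverage(obs, pred, c(2, 5, 10))
  expect_true(all(diff(cov) >= 0))
  analytic <- 2 * pnorm(log(c(2, 5, 10)) / sdlog) - 1
  expect_equal(unname(cov), analytic, tolerance = 0.01)
})

test_that("model_size_curve tracks the stepwise entry path", {
  set.seed(12)
  x <- matrix(rnorm(60 * 6), 60, 6,
              dimnames = list(NULL, sprintf("x%d", 1:6)))
  y <- 2 * x[, 1] - x[, 2]          # noiseless 2-term truth
  ds <- list(table = x, response = y)
  curve <- model_size_curve(ds)
  expect_identical(nrow(curve), 2L)
  expect_equal(curve$r2_adj[2], 1, tolerance = 1e-10)

  sw <- fit_stepwise(ds)
  expect_identical(nrow(curve), sum(sw$log$action == "enter"))

  empty <- model_size_curve(list(table = x, response = rnorm(60) * 0 + 5),
                            stepwise_config(p_enter = 1e-9, p_remove = 1e-8))
  expect_identical(nrow(empty), 0L)
})

test_that("validate_model assembles a coherent report", {
  sp <- synthetic_spec(seed = 30, n_descriptors = 30, n_constant = 2,
                       n_sparse = 2, n_duplicated = 2, n_count = 3)
  tab <- generate_descriptor_matrix(sp)
  resp <- generate_response(tab, sp)
  ds <- build_dataset(tab, resp, seed = 30)
  scr <- screen_descriptors(ds$table, response = ds$response)
  ds$table <- scr$table
  sw <- fit_stepwise(ds)
  rep <- validate_model(sw$model, ds)
  expect_lte(rep$r2_train, 1)
  expect_gte(rep$dw, 0); expect_lte(rep$dw, 4)
  expect_true(all(rep$vif >= 1))
  expect_lte(rep$q2, rep$r2_train)  # PRESS >= SS_res for LOO
  expect_true(all(diff(rep$coverage) >= 0))
  expect_true(all(rep$coverage >= 0 & rep$coverage <= 1))
})
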