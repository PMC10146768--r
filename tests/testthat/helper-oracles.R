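# Independent oracles: deliberately coded against different primitives
# (solve(), lm(), explicit loops) than the implementation's lm.fit path.

oracle_ols <- function(X, y) {
  Xd <- cbind(1, as.matrix(X))
  unname(drop(solve(t(Xd) %*% Xd, t(Xd) %*% y)))
}

oracle_loo_q2 <- function(x, y) {
  n <- length(y)
  press <- 0
  for (i in seq_len(n)) {
    df <- data.frame(y = y[-i], x[-i, , drop = FALSE])
    fit <- lm(y ~ ., data = df)
    pred <- predict(fit, newdata = data.frame(x[i, , drop = FALSE]))
    press <- press + (y[i] - pred)^2
  }
  unname(1 - press / sum((y - mean(y))^2))
}

oracle_vif <- function(x) {
  vapply(seq_len(ncol(x)), function(j) {
    r2 <- summary(lm(x[, j] ~ x[, -j]))$r.squared
    1 / (1 - r2)
  }, numeric(1))
}

oracle_roy <- function(obs, pred) {
  c(k = as.numeric(coef(lm(obs ~ 0 + pred))),
    k_prime = as.numeric(coef(lm(pred ~ 0 + obs))))
}

rand_table <- function(n, p, seed, prefix = "D") {
  set.seed(seed)
  descriptor_table(matrix(rnorm(n * p), n, p),
                   chem_ids = sprintf("c%03d", seq_len(n)),
                   descriptor_names = sprintf("%s%02d", prefix, seq_len(p)))
}

write_temp_csv <- function(df, name = "t.csv") {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
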