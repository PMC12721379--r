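# Shared fixtures: everything is generated in code at test time.

tiny_config <- function(...) {
  args <- list(n_samples = 60, n_species = 16, n_clusters = 2,
               total_reads_per_sample = 2e4, seed = 101)
  args[names(list(...))] <- list(...)
  do.call(generator_config, args)
}

# Hand-built stratified table: strata as (sample, ec, species, cpm) rows.
strat_df <- function(...) {
  m <- rbind(...)
  data.frame(sample = m[, 1], ec = m[, 2], species = m[, 3],
             cpm = as.numeric(m[, 4]), stringsAsFactors = FALSE)
}

# Independent Spearman oracle: average ranks computed by hand, then the
# Pearson product-moment formula evaluated from raw sums.
spearman_oracle <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  n <- length(x)
  num <- n * sum(rx * ry) - sum(rx) * sum(ry)
  den <- sqrt(n * sum(rx^2) - sum(rx)^2) * sqrt(n * sum(ry^2) - sum(ry)^2)
  num / den
}

# Independent OLS oracle: normal equations + t / F distributions.
ols_oracle <- function(y, X) {
  X1 <- cbind(`(Intercept)` = 1, as.matrix(X))
  n <- length(y); p <- ncol(X1) - 1
  beta <- solve(t(X1) %*% X1, t(X1) %*% y)
  resid <- y - X1 %*% beta
  rss <- sum(resid^2)
  sigma2 <- rss / (n - p - 1)
  se <- sqrt(diag(solve(t(X1) %*% X1)) * sigma2)
  tstat <- beta[, 1] / se
  pvals <- 2 * pt(-abs(tstat), df = n - p - 1)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  fstat <- ((tss - rss) / p) / sigma2
  list(coefficients = beta[, 1], p = pvals, adj_r2 = adj_r2,
       model_p = pf(fstat, p, n - p - 1, lower.tail = FALSE))
}
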