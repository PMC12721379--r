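test_that("contributions are percentages of the community total", {
  mt <- stratified_table(
    strat_df(c("S1", "3.2.1.18", "A", "5"),
             c("S1", "3.2.1.18", "B", "11"),
             c("S1", "3.2.1.18", "UNCLASSIFIED", "4"),
             c("S2", "3.2.1.18", "B", "7")))
  contrib <- contributions(mt)
  get <- function(s, sp)
    contrib$contribution[contrib$sample == s & contrib$species == sp]
  expect_equal(get("S1", "A"), 25)        # 5 of 20
  expect_equal(get("S2", "B"), 100)       # sole transcriber
  # closure: species + unclassified contributions sum to 100
  s1 <- contrib[contrib$sample == "S1", ]
  expect_equal(sum(s1$contribution), 100, tolerance = 1e-9)
  # classified-only denominator excludes the unclassified stratum
  c2 <- contributions(mt, classified_only = TRUE)
  expect_equal(c2$contribution[c2$sample == "S1" & c2$species == "A"],
               100 * 5 / 16)
})

test_that("contribution closure holds on generated data", {
  sim <- simulate_community(tiny_config(n_samples = 30))
  contrib <- contributions(sim$transcription)
  sums <- tapply(contrib$contribution,
                 paste(contrib$sample, contrib$ec), sum)
  expect_lt(max(abs(sums - 100)), 1e-6)
})

test_that("OLS fits match the normal-equations oracle to 1e-8", {
  set.seed(88)
  for (rep in 1:5) {
    n <- sample(15:40, 1)
    p <- sample(1:4, 1)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(paste0("s", 1:n), paste0("x", 1:p)))
    y <- rnorm(n, X %*% rnorm(p))
    oracle <- ols_oracle(y, X)
    f <- glycoguild:::ols_fit(y, as.data.frame(X), "y",
                              colnames(X))
    expect_equal(unname(f$coefficients),
                 unname(oracle$coefficients[-1]), tolerance = 1e-8)
    expect_equal(unname(f$coef_p), unname(oracle$p[-1]),
                 tolerance = 1e-8)
    expect_equal(f$adj_r2, oracle$adj_r2, tolerance = 1e-8)
    expect_equal(f$model_p, oracle$model_p, tolerance = 1e-8)
  }
})

test_that("perfect linear data give adjusted R^2 of 1", {
  samples <- paste0("S", 1:10)
  x <- 1:10
  clr <- matrix(x, 10, 1, dimnames = list(samples, "A"))
  contrib <- data.frame(sample = samples, ec = "3.2.1.18", species = "A",
                        contribution = 2 * x + 1)
  fit <- suppressWarnings(  # summary.lm warns on an exact fit
    abundance_driven_fit(contrib, clr, "3.2.1.18", "A"))
  expect_equal(fit$adj_r2, 1, tolerance = 1e-10)
  expect_lt(fit$model_p, 1e-12)
  expect_equal(unname(fit$coefficients[1]), 2, tolerance = 1e-10)
})

test_that("independent noise gives near-zero adjusted R^2", {
  set.seed(99)
  samples <- paste0("S", 1:200)
  clr <- matrix(rnorm(200), 200, 1, dimnames = list(samples, "A"))
  contrib <- data.frame(sample = samples, ec = "3.2.1.18", species = "A",
                        contribution = runif(200, 0, 100))
  fit <- abundance_driven_fit(contrib, clr, "3.2.1.18", "A")
  expect_lt(abs(fit$adj_r2), 0.05)
})

test_that("degenerate fits are skipped with a reason", {
  samples <- paste0("S", 1:12)
  clr <- matrix(1, 12, 1, dimnames = list(samples, "A"))
  contrib <- data.frame(sample = samples, ec = "3.2.1.18", species = "A",
                        contribution = runif(12))
  f <- abundance_driven_fit(contrib, clr, "3.2.1.18", "A")
  expect_s3_class(f, "skipped_fit")
  expect_match(f$reason, "constant")
  f2 <- abundance_driven_fit(contrib[1:5, ], clr[1:5, , drop = FALSE],
                             "3.2.1.18", "A")
  expect_match(f2$reason, "few samples")
})

test_that("response-predictor models exclude self-abundance", {
  sim <- simulate_community(tiny_config(n_samples = 120))
  cfg <- tiny_config(n_samples = 120)
  clr <- clr_transform(sim$abundance)
  contrib <- contributions(sim$transcription, cfg$catalog)
  pairs <- prevalent_pairs(sim$transcription, cfg$catalog)
  ec <- pairs$ec[1]
  tr <- pairs$species[pairs$ec == ec]
  res <- response_predictor_fit(contrib, clr, ec, tr)
  expect_true(all(res$edges$predictor != res$edges$response))
  expect_true(all(res$edges$p < 0.05))
  expect_true(all(res$edges$sign %in% c("positive", "negative")))
  expect_true(all((res$edges$coefficient < 0) ==
                    (res$edges$sign == "negative")))
})

test_that("independent transcribers yield no edges; planted suppression is found", {
  # two transcribers with independent abundance and transcription
  set.seed(7)
  samples <- paste0("S", 1:150)
  clr <- matrix(rnorm(300), 150, 2, dimnames = list(samples, c("A", "B")))
  contrib <- rbind(
    data.frame(sample = samples, ec = "3.2.1.18", species = "A",
               contribution = runif(150, 0, 50)),
    data.frame(sample = samples, ec = "3.2.1.18", species = "B",
               contribution = runif(150, 0, 50)))
  res <- response_predictor_fit(contrib, clr, "3.2.1.18", c("A", "B"),
                                alpha = 0.01)
  expect_equal(nrow(res$edges), 0)

  # planted suppression A -> B at n = 300
  cfg <- generator_config(n_samples = 300, seed = 17)
  sim <- simulate_community(cfg)
  clr <- clr_transform(sim$abundance)
  contrib <- contributions(sim$transcription, cfg$catalog)
  pairs <- prevalent_pairs(sim$transcription, cfg$catalog)
  rp <- response_predictor_networks(contrib, clr, pairs)
  planted <- sim$truth$planted_edges
  hit <- paste(rp$edges$ec, rp$edges$predictor, rp$edges$response,
               rp$edges$sign) %in%
    paste(planted$ec, planted$predictor, planted$response, planted$sign)
  found <- paste(planted$ec, planted$predictor, planted$response) %in%
    paste(rp$edges$ec[rp$edges$sign == "negative"],
          rp$edges$predictor[rp$edges$sign == "negative"],
          rp$edges$response[rp$edges$sign == "negative"])
  expect_gt(mean(found), 0.8)
})

test_that("consensus labels follow the both-signs rule", {
  e <- data.frame(
    ec = c("3.2.1.18", "3.2.1.51", "3.2.1.52", "3.2.1.96",
           "3.2.1.51", "3.2.1.22", "3.2.1.23"),
    predictor = c("A", "A", "A", "A", "R", "R", "B"),
    response = c("B", "B", "B", "B", "C", "C", "S"),
    coefficient = c(-1, -2, -1, -3, -0.5, 0.5, 2),
    p = 0.01,
    sign = c("negative", "negative", "negative", "negative",
             "negative", "positive", "positive"))
  cons <- consensus_edges(e)
  ab <- cons[cons$predictor == "A" & cons$response == "B", ]
  expect_equal(ab$label, "always_negative")
  expect_equal(ab$n_negative, 4)
  rc <- cons[cons$predictor == "R" & cons$response == "C", ]
  expect_equal(rc$label, "mixed")
  expect_true(rc$n_positive > 0 && rc$n_negative > 0)
  bs <- cons[cons$predictor == "B" & cons$response == "S", ]
  expect_equal(bs$label, "always_positive")
  expect_equal(nrow(consensus_edges(e[0, ])), 0)
  # mixed <=> both signs, across all rows
  expect_equal(cons$label == "mixed",
               cons$n_positive > 0 & cons$n_negative > 0)
})

test_that("ecology summary medians, averages and classes are correct", {
  fits <- data.frame(
    ec = rep(c("e1", "e2", "e3"), 2),
    species = rep(c("A", "B"), each = 3),
    adj_r2 = c(0.1, 0.3, 0.5, 0.0, 0.05, 0.1),
    skipped = FALSE)
  fits$ec <- sprintf("3.2.1.%d", rep(c(18, 51, 52), 2))
  edges <- data.frame(ec = "3.2.1.18", predictor = "A", response = "B",
                      coefficient = -1, p = 0.01, sign = "negative")
  eligible <- expand.grid(ec = sprintf("3.2.1.%d", c(18, 51, 52)),
                          species = c("A", "B"),
                          stringsAsFactors = FALSE)
  s <- ecology_summary(fits, edges, eligible)
  a <- s$species[s$species$species == "A", ]
  b <- s$species[s$species$species == "B", ]
  expect_equal(a$median_adj_r2, 0.3)
  expect_equal(a$class, "competitive")
  expect_equal(b$class, "opportunistic")
  expect_equal(a$avg_inhibited, 1 / 3)   # one negative edge, 3 networks
  expect_equal(b$avg_inhibited, 0)       # no negative out-edges
  expect_equal(a$avg_facilitated, 0)
})
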