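clr_of <- function(m) {
  # treat an arbitrary numeric matrix as already-transformed values
  dimnames(m) <- dimnames(m) %||%
    list(paste0("s", seq_len(nrow(m))), paste0("sp", seq_len(ncol(m))))
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("spearman matrix matches hand-evaluated rank correlations", {
  x <- c(1, 2, 3)
  y <- c(3, 1, 2)
  m <- cbind(a = x, b = y, c = x)
  rownames(m) <- paste0("s", 1:3)
  rho <- spearman_matrix(m, min_present_samples = 0)
  expect_equal(rho["a", "b"], -0.5, tolerance = 1e-12)  # 1 - 6*9/(3*8)
  expect_equal(rho["a", "c"], 1)
  expect_equal(diag(rho), c(a = 1, b = 1, c = 1))
})

test_that("spearman agrees with the independent rank oracle under ties", {
  set.seed(5)
  m <- matrix(sample(1:4, 60, replace = TRUE), 15, 4,
              dimnames = list(paste0("s", 1:15), paste0("sp", 1:4)))
  rho <- spearman_matrix(m, min_present_samples = 0)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(rho[i, j], spearman_oracle(m[, i], m[, j]),
                 tolerance = 1e-8)
  }
})

test_that("constant species give missing correlations, not edges", {
  m <- cbind(a = c(1, 2, 3, 4), b = c(2, 2, 2, 2), c = c(4, 3, 2, 1))
  rownames(m) <- paste0("s", 1:4)
  rho <- spearman_matrix(m, min_present_samples = 0)
  expect_true(is.na(rho["a", "b"]))
  null <- list(ci = c(-0.5, 0.5))
  edges <- call_edges(rho, null)
  expect_false(any(edges$species_a == "b" | edges$species_b == "b"))
})

test_that("presence filter drops sparse species before correlating", {
  set.seed(1)
  counts <- matrix(rpois(30 * 3, 10), 30, 3,
                   dimnames = list(paste0("s", 1:30), c("a", "b", "c")))
  counts[6:30, "c"] <- 0
  rho <- spearman_matrix(clr_transform(counts), counts = counts,
                         min_present_samples = 20)
  expect_setequal(colnames(rho), c("a", "b"))
})

test_that("permutation null is seeded, symmetric and sized correctly", {
  set.seed(2)
  m <- clr_of(matrix(rnorm(100 * 6), 100, 6))
  n1 <- permutation_null(m, n_reps = 200, seed = 9)
  n2 <- permutation_null(m, n_reps = 200, seed = 9)
  expect_identical(n1$ci, n2$ci)
  expect_length(n1$rho, 200 * choose(6, 2))
  # iid input: interval approximately symmetric about zero
  expect_lt(abs(n1$ci[1] + n1$ci[2]), 0.05)
  expect_lt(n1$ci[1], 0)
  expect_gt(n1$ci[2], 0)
  expect_error(permutation_null(m, n_reps = 50), ">= 100")
})

test_that("edge calling enforces significance, positivity and min rho", {
  rho <- matrix(c(1, 0.5, -0.6, 0.15,
                  0.5, 1, 0.1, 0.25,
                  -0.6, 0.1, 1, 0.3,
                  0.15, 0.25, 0.3, 1), 4, 4,
                dimnames = list(letters[1:4], letters[1:4]))
  null <- list(ci = c(-0.12, 0.12))
  edges <- call_edges(rho, null)
  get <- function(a, b) edges[edges$species_a == a & edges$species_b == b, ]
  expect_true(get("a", "b")$retained)              # 0.5, outside, >= 0.2
  expect_true(get("a", "c")$significant)           # -0.6 significant...
  expect_false(get("a", "c")$retained)             # ...but negative
  expect_true(get("a", "d")$significant)           # 0.15 outside ci...
  expect_false(get("a", "d")$retained)             # ...but < 0.2
  expect_false(get("b", "c")$significant)          # 0.1 inside ci
  expect_true(all(edges$retained <= edges$significant))
})

test_that("first-neighbor subgraph follows the chain example", {
  edges <- data.frame(species_a = c("A", "B"), species_b = c("B", "C"),
                      rho = c(0.5, 0.5), significant = TRUE,
                      retained = TRUE)
  net <- degrader_subgraph(edges, "A")
  expect_setequal(net$nodes$species, c("A", "B"))  # C is not a neighbor
  expect_equal(nrow(net$edges), 1)
  expect_warning(iso <- degrader_subgraph(edges[0, ], "A"), "isolated")
  expect_equal(iso$nodes$species, "A")             # isolated degrader kept
})

test_that("greedy modularity separates cliques, keeps singletons", {
  clique <- function(v) t(combn(v, 2))
  e <- rbind(clique(c("a1", "a2", "a3")), clique(c("b1", "b2", "b3")))
  edges <- data.frame(species_a = e[, 1], species_b = e[, 2], rho = 0.5,
                      significant = TRUE, retained = TRUE)
  net <- degrader_subgraph(edges, c("a1", "b1", "z"))
  net <- cluster_fast_greedy_network(net)
  cl <- setNames(net$nodes$cluster, net$nodes$species)
  expect_equal(length(unique(cl)), 3)              # 2 cliques + singleton
  expect_equal(length(unique(cl[c("a1", "a2", "a3")])), 1)
  expect_equal(length(unique(cl[c("b1", "b2", "b3")])), 1)
  expect_false(cl["a1"] == cl["b1"])
  # single clique collapses to one cluster
  one <- degrader_subgraph(edges[1:3, ], "a1")
  one <- cluster_fast_greedy_network(one)
  expect_equal(length(unique(one$nodes$cluster)), 1)
  # reported partition at least as modular as the trivial one
  g <- igraph::graph_from_data_frame(net$edges[, 1:2], directed = FALSE,
                                     vertices = net$nodes$species)
  trivial <- igraph::modularity(g, rep(1, nrow(net$nodes)))
  expect_gte(attr(net, "modularity"), trivial)
})

test_that("species relabeling permutes but does not change the edges", {
  cfg <- tiny_config(n_samples = 80)
  sim <- simulate_abundances(cfg)
  clr <- clr_transform(sim$abundance)
  rho <- spearman_matrix(clr, min_present_samples = 0)
  null <- permutation_null(clr, n_reps = 150, seed = 3, keep_null = FALSE)
  e1 <- call_edges(rho, null)
  perm <- sample(colnames(clr))
  clr2 <- clr[, perm]
  rho2 <- spearman_matrix(clr2, min_present_samples = 0)
  e2 <- call_edges(rho2, null)
  key <- function(e) {
    r <- e[e$retained, ]
    sort(paste(pmin(r$species_a, r$species_b),
               pmax(r$species_a, r$species_b)))
  }
  expect_identical(key(e1), key(e2))
})

test_that("planted blocks are recovered by the full network stage", {
  cfg <- generator_config(n_samples = 300, seed = 31)
  sim <- simulate_abundances(cfg)
  degr <- names(cfg$roles)[cfg$roles != "nondegrader"]
  net <- cooccurrence_network(sim$abundance, degr, n_reps = 300,
                              seed = 31)
  truth <- sim$truth$cluster_assignment[net$nodes$species]
  ari <- mclust::adjustedRandIndex(net$nodes$cluster, truth)
  expect_gte(ari, 0.8)
  # every node is a degrader or linked to one
  non_deg <- net$nodes$species[!net$nodes$is_degrader]
  touching <- unique(c(
    net$edges$species_b[net$edges$species_a %in% degr],
    net$edges$species_a[net$edges$species_b %in% degr]))
  expect_true(all(non_deg %in% touching))
})
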