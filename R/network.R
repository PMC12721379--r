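#' Pairwise Spearman correlation matrix of clr abundances
#'
#' Computes all pairwise Spearman rank correlations between species
#' columns (average ranks for ties). Species detected (count > 0) in
#' fewer than `min_present_samples` samples are dropped before
#' correlating: sparse species make rank correlations unstable, and
#' robust network inference needs on the order of 20 or more informative
#' samples per taxon. Constant columns yield `NA` correlations and are
#' excluded from edge calling downstream.
#'
#' @param clr numeric matrix of clr values, samples x species (see
#'   [clr_transform()]).
#' @param counts optional read-count matrix of the same shape used for
#'   the presence filter; `NULL` disables the filter.
#' @param min_present_samples minimum number of samples with nonzero
#'   counts (default 20).
#' @return symmetric correlation matrix with unit diagonal over the
#'   retained species.
#' @export
spearman_matrix <- function(clr, counts = NULL, min_present_samples = 20) {
  clr <- as.matrix(clr)
  if (nrow(clr) < 3) stop("need at least 3 samples")
  if (!is.null(counts)) {
    counts <- as.matrix(counts)[rownames(clr), colnames(clr), drop = FALSE]
    keep <- colSums(counts > 0) >= min_present_samples
    clr <- clr[, keep, drop = FALSE]
  }
  r <- apply(clr, 2, rank)
  const <- apply(clr, 2, function(v) length(unique(v)) == 1)
  rho <- suppressWarnings(stats::cor(r))
  rho[const, ] <- NA
  rho[, const] <- NA
  diag(rho) <- ifelse(const, NA, 1)
  rho
}

#' Permutation null distribution for Spearman co-occurrence
#'
#' Builds a null for the pairwise correlations by independently permuting
#' each species' values across samples (destroying every cross-species
#' association while preserving each species' marginal distribution),
#' recomputing all pairwise Spearman correlations, and pooling the
#' shuffled correlations of all replicates into one global null. The
#' confidence interval is the central `ci_level` interval of the pooled
#' null; observed correlations outside it are called significant.
#'
#' @param clr clr matrix, samples x species.
#' @param n_reps number of shuffle replicates (default 1000; fewer than
#'   100 is rejected, the interval tails would be unstable).
#' @param ci_level central interval mass (default 0.99).
#' @param seed integer seed; the null is reproducible given the seed.
#' @param keep_null if `TRUE` (default) the pooled correlations are
#'   returned in the object.
#' @return a `null_distribution`: list with `ci` (lower, upper),
#'   `n_reps`, `ci_level`, `seed`, `n_pairs` and (optionally) `rho` (the
#'   pooled values, length `n_reps * n_pairs`).
#' @export
permutation_null <- function(clr, n_reps = 1000, ci_level = 0.99,
                             seed = 1L, keep_null = TRUE) {
  if (n_reps < 100) stop("n_reps must be >= 100 (unstable interval tails)")
  clr <- as.matrix(clr)
  n <- nrow(clr)
  p <- ncol(clr)
  if (p < 2) stop("need at least 2 species")
  # Spearman is rank-based, so permuting a column and re-ranking equals
  # permuting its ranks: rank once, then shuffle ranks.
  r <- apply(clr, 2, rank)
  const <- apply(clr, 2, function(v) length(unique(v)) == 1)
  ut <- upper.tri(matrix(0, p, p))
  pair_ok <- ut & !outer(const, const, `|`)
  n_pairs <- sum(pair_ok)
  pooled <- with_seed(seed, {
    out <- vector("list", n_reps)
    for (b in seq_len(n_reps)) {
      rp <- r
      for (j in seq_len(p)) rp[, j] <- rp[sample.int(n), j]
      rho <- suppressWarnings(stats::cor(rp))
      out[[b]] <- rho[pair_ok]
    }
    unlist(out)
  })
  alpha <- (1 - ci_level) / 2
  ci <- unname(stats::quantile(pooled, c(alpha, 1 - alpha), na.rm = TRUE))
  structure(
    list(ci = ci, n_reps = n_reps, ci_level = ci_level, seed = seed,
         n_pairs = n_pairs, rho = if (keep_null) pooled else NULL),
    class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "permutation null: %d reps x %d pairs; %.0f%% CI [%.4f, %.4f]\n",
    x$n_reps, x$n_pairs, 100 * x$ci_level, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Call significant, retained co-occurrence edges
#'
#' An observed correlation is *significant* when it falls outside the
#' null confidence interval, and *retained* as a network edge when it is
#' additionally positive and at least `min_rho`: negative and weak
#' positive correlations are removed so that edges reflect strong
#' co-occurrence.
#'
#' @param rho_matrix symmetric Spearman matrix from [spearman_matrix()].
#' @param null a [permutation_null()] result.
#' @param min_rho retention threshold on the correlation (default 0.2).
#' @return data.frame of unordered pairs: `species_a`, `species_b`,
#'   `rho`, `significant`, `retained` (NA correlations are skipped).
#' @export
call_edges <- function(rho_matrix, null, min_rho = 0.2) {
  sp <- colnames(rho_matrix)
  idx <- which(upper.tri(rho_matrix), arr.ind = TRUE)
  rho <- rho_matrix[idx]
  keep <- !is.na(rho)
  idx <- idx[keep, , drop = FALSE]
  rho <- rho[keep]
  significant <- rho < null$ci[1] | rho > null$ci[2]
  data.frame(
    species_a = sp[idx[, 1]], species_b = sp[idx[, 2]], rho = rho,
    significant = significant,
    retained = significant & rho >= min_rho,
    stringsAsFactors = FALSE)
}

#' Restrict edges to degraders and their first neighbors
#'
#' First neighbors are species sharing a retained edge with a degrader.
#' The network keeps the degraders (isolated degraders stay as isolated
#' nodes), their first neighbors, and every retained edge whose two
#' endpoints are both kept.
#'
#' @param edges edge table from [call_edges()].
#' @param degraders character vector of degrader species.
#' @return a `cooccurrence_network`: list with `nodes` (species,
#'   is_degrader, cluster = NA until clustered) and `edges` (retained
#'   edges within the node set).
#' @export
degrader_subgraph <- function(edges, degraders) {
  if (length(degraders) == 0) stop("empty degrader set")
  ret <- edges[edges$retained, , drop = FALSE]
  touches <- ret$species_a %in% degraders | ret$species_b %in% degraders
  neighbors <- setdiff(unique(c(ret$species_a[touches],
                                ret$species_b[touches])), degraders)
  nodes <- sort(unique(c(degraders, neighbors)))
  keep <- ret$species_a %in% nodes & ret$species_b %in% nodes
  sub <- ret[keep, , drop = FALSE]
  if (nrow(sub) == 0) {
    warning("no degrader has retained edges; network of isolated nodes")
  }
  rownames(sub) <- NULL
  structure(
    list(nodes = data.frame(species = nodes,
                            is_degrader = nodes %in% degraders,
                            cluster = NA_integer_,
                            stringsAsFactors = FALSE),
         edges = sub),
    class = "cooccurrence_network")
}

#' Cluster a co-occurrence network by greedy modularity
#'
#' Runs Clauset-Newman-Moore greedy modularity optimization (igraph's
#' fast-greedy algorithm) on the unweighted presence/absence adjacency of
#' the network. Vertices are added in lexicographic order so results are
#' reproducible; isolated nodes form singleton clusters. Cluster ids are
#' renumbered by first appearance in lexicographic node order.
#'
#' @param net a [degrader_subgraph()] network.
#' @return the network with `nodes$cluster` filled and attributes
#'   `modularity` (of the reported partition) recorded.
#' @export
cluster_fast_greedy_network <- function(net) {
  stopifnot(inherits(net, "cooccurrence_network"))
  nodes <- sort(net$nodes$species)
  g <- igraph::graph_from_data_frame(
    net$edges[, c("species_a", "species_b")], directed = FALSE,
    vertices = nodes)
  comm <- igraph::cluster_fast_greedy(g, weights = NULL)
  # cut the agglomeration path at its modularity maximum ourselves; on
  # exact ties prefer the coarser partition (e.g. one clique -> one
  # cluster)
  path <- comm$modularity
  best <- max(which(path >= max(path) - 1e-12))
  memb <- igraph::cut_at(comm, no = igraph::vcount(g) - (best - 1))
  memb <- stats::setNames(as.integer(memb), igraph::V(g)$name)
  # renumber by first appearance over sorted node names
  relabel <- stats::setNames(seq_along(unique(memb[nodes])),
                             unique(memb[nodes]))
  memb <- stats::setNames(as.integer(relabel[as.character(memb[nodes])]),
                          nodes)
  net$nodes$cluster <- unname(memb[net$nodes$species])
  attr(net, "modularity") <-
    igraph::modularity(g, memb[igraph::V(g)$name])
  net
}

#' Build the degrader co-occurrence network end to end
#'
#' Convenience wrapper: clr transform, presence filter, Spearman matrix,
#' permutation null, edge calling, first-neighbor restriction, and
#' greedy-modularity clustering.
#'
#' @param abund an [abundance_table()].
#' @param degraders degrader species (e.g. the `prevalent_versatile` set
#'   from [call_degraders()]).
#' @param min_present_samples presence filter (default 20).
#' @param n_reps,ci_level,seed passed to [permutation_null()].
#' @param min_rho edge retention threshold (default 0.2).
#' @param pseudocount passed to [clr_transform()].
#' @return a clustered `cooccurrence_network` with the edge table, the
#'   null summary in attribute `"null"`, and all correlations in
#'   attribute `"all_edges"`.
#' @export
cooccurrence_network <- function(abund, degraders,
                                 min_present_samples = 20,
                                 n_reps = 1000, ci_level = 0.99,
                                 seed = 1L, min_rho = 0.2,
                                 pseudocount = 1) {
  clr <- clr_transform(abund, pseudocount)
  rho <- spearman_matrix(clr, counts = abund$read_counts,
                         min_present_samples = min_present_samples)
  clr_kept <- clr[, colnames(rho), drop = FALSE]
  null <- permutation_null(clr_kept, n_reps = n_reps,
                           ci_level = ci_level, seed = seed,
                           keep_null = FALSE)
  edges <- call_edges(rho, null, min_rho = min_rho)
  net <- degrader_subgraph(edges, intersect(degraders, colnames(rho)))
  net <- cluster_fast_greedy_network(net)
  attr(net, "null") <- null
  attr(net, "all_edges") <- edges
  net
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  k <- length(unique(stats::na.omit(x$nodes$cluster)))
  cat(sprintf(paste0(
    "cooccurrence_network: %d nodes (%d degraders), %d retained edges",
    "%s\n"),
    nrow(x$nodes), sum(x$nodes$is_degrader), nrow(x$edges),
    if (k > 0) sprintf(", %d clusters (modularity %.3f)", k,
                       attr(x, "modularity") %||% NA) else ""))
  invisible(x)
}

#' @export
summary.cooccurrence_network <- function(object, ...) {
  tab <- table(cluster = object$nodes$cluster,
               degrader = object$nodes$is_degrader)
  cat("Nodes per cluster (degraders vs neighbors):\n")
  print(tab)
  invisible(tab)
}

#' Plot a co-occurrence network
#'
#' Draws the network with igraph: degrader nodes enlarged, node color by
#' cluster, edge width by correlation strength.
#'
#' @param x a `cooccurrence_network`.
#' @param ... passed to [igraph::plot.igraph()].
#' @export
plot.cooccurrence_network <- function(x, ...) {
  g <- igraph::graph_from_data_frame(
    x$edges[, c("species_a", "species_b", "rho")], directed = FALSE,
    vertices = x$nodes)
  igraph::plot.igraph(
    g,
    vertex.size = ifelse(igraph::V(g)$is_degrader, 8, 4),
    vertex.color = igraph::V(g)$cluster,
    vertex.label = ifelse(igraph::V(g)$is_degrader,
                          igraph::V(g)$name, NA),
    vertex.label.cex = 0.6,
    edge.width = 2 * abs(igraph::E(g)$rho), ...)
  invisible(x)
}

#' Export a network as edge and node tables
#'
#' Writes `edges.tsv`, `nodes.tsv` and `null_summary.tsv` plus a GraphML
#' file readable by external viewers.
#'
#' @param net a `cooccurrence_network`.
#' @param outdir output directory.
#' @return invisibly, the written paths.
#' @export
export_network <- function(net, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(outdir, "edges.tsv")
  p2 <- file.path(outdir, "nodes.tsv")
  write_tsv_artifact(net$edges, p1, "retained co-occurrence edges")
  write_tsv_artifact(net$nodes, p2, "network nodes with cluster labels")
  paths <- c(p1, p2)
  null <- attr(net, "null")
  if (!is.null(null)) {
    p3 <- file.path(outdir, "null_summary.tsv")
    write_tsv_artifact(
      data.frame(ci_lower = null$ci[1], ci_upper = null$ci[2],
                 n_reps = null$n_reps, ci_level = null$ci_level,
                 seed = null$seed),
      p3, "permutation null summary")
    paths <- c(paths, p3)
  }
  g <- igraph::graph_from_data_frame(
    net$edges[, c("species_a", "species_b", "rho")], directed = FALSE,
    vertices = net$nodes)
  p4 <- file.path(outdir, "network.graphml")
  igraph::write_graph(g, p4, format = "graphml")
  invisible(c(paths, p4))
}
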