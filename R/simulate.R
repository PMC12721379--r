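#' Configuration for the synthetic community generator
#'
#' The generator emulates the structure the downstream analyses are built
#' to detect: (i) compositional read-count tables whose species fall into
#' block-correlated co-occurrence clusters, and (ii) species-stratified EC
#' transcription with two planted regimes. *Competitive* degraders couple
#' transcription linearly to their own clr abundance (abundance-driven
#' transcription); *opportunistic* degraders transcribe at a baseline rate
#' that is logistically suppressed as the summed clr abundance of the
#' competitive transcribers of the same EC rises (transcription decoupled
#' from their own abundance). Nondegraders transcribe nothing.
#'
#' Default role assignment places competitive degraders in the first half
#' of the co-occurrence clusters and opportunists in the second half, so
#' an opportunist's own abundance is uncorrelated with the abundance of
#' its suppressors; EC repertoires are dealt round-robin (3 active
#' catalog ECs per degrader), giving every EC both competitive and
#' opportunistic transcribers.
#'
#' @param n_samples number of samples (default 300).
#' @param n_species number of species (default 40).
#' @param n_clusters number of planted co-occurrence blocks (default 4).
#' @param within_cluster_rho latent correlation inside a block, in
#'   `[0, 1)` (default 0.8; 0 between blocks).
#' @param total_reads_per_sample multinomial read depth (default 1e5).
#' @param ec_repertoire named list species -> character vector of EC ids;
#'   `NULL` uses the default round-robin assignment.
#' @param roles named character vector species -> one of `"competitive"`,
#'   `"opportunistic"`, `"nondegrader"`; `NULL` uses the default.
#' @param coupling_strength cpm emitted per clr unit by competitive
#'   species (default 8).
#' @param suppression_strength steepness of the logistic suppression of
#'   opportunists by competitor clr abundance (default 1.2; 0 disables).
#' @param opportunist_baseline unsuppressed opportunist rate, cpm
#'   (default 25).
#' @param expression_offset clr offset at which a competitive species'
#'   expected transcription reaches zero (default -4: species have to be
#'   reasonably abundant to transcribe).
#' @param noise_sd Gaussian cpm noise on every stratum (default 3).
#' @param unclassified_fraction UNCLASSIFIED remainder added to each
#'   (sample, EC) total, as a fraction of the species strata (default
#'   0.02).
#' @param gh_ratio planted ratio of other glycoside hydrolase ECs to
#'   mucin-catalog ECs in each degrader's gene repertoire (default 2).
#' @param mu_sd standard deviation of species mean log-abundances
#'   (default 1.5); latent per-sample log fluctuations have unit scale.
#' @param seed integer RNG seed baked into the configuration
#'   (default 20240901).
#' @param catalog an [load_ec_catalog()] catalog supplying the EC universe
#'   for default repertoires.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_samples = 300,
                             n_species = 40,
                             n_clusters = 4,
                             within_cluster_rho = 0.8,
                             total_reads_per_sample = 1e5,
                             ec_repertoire = NULL,
                             roles = NULL,
                             coupling_strength = 8,
                             suppression_strength = 1.2,
                             opportunist_baseline = 25,
                             expression_offset = -4,
                             noise_sd = 3,
                             unclassified_fraction = 0.02,
                             gh_ratio = 2,
                             mu_sd = 1.5,
                             seed = 20240901,
                             catalog = load_ec_catalog()) {
  if (within_cluster_rho < 0 || within_cluster_rho >= 1) {
    stop("within_cluster_rho must be in [0, 1)")
  }
  if (n_clusters > n_species) stop("n_clusters must be <= n_species")
  species <- sprintf("Species_%03d", seq_len(n_species))
  cluster <- rep(seq_len(n_clusters), length.out = 0) # filled below
  # contiguous, near-equal blocks
  sizes <- diff(round(seq(0, n_species, length.out = n_clusters + 1)))
  cluster <- rep(seq_len(n_clusters), times = sizes)
  names(cluster) <- species

  ecs <- catalog$ec_id[catalog$active]
  if (is.null(roles)) {
    roles <- rep("nondegrader", n_species)
    names(roles) <- species
    comp_clusters <- seq_len(max(1, floor(n_clusters / 2)))
    n_deg_per_cluster <- max(1, round(0.4 * min(sizes)))
    for (k in seq_len(n_clusters)) {
      members <- species[cluster == k]
      chosen <- utils::head(members, n_deg_per_cluster)
      roles[chosen] <- if (k %in% comp_clusters) "competitive" else
        "opportunistic"
    }
    if (!any(roles == "opportunistic")) {
      # single-cluster degenerate case: split the chosen degraders
      deg <- names(roles)[roles == "competitive"]
      if (length(deg) > 1) {
        roles[deg[seq(2, length(deg), by = 2)]] <- "opportunistic"
      }
    }
  } else {
    roles <- roles[species]
    names(roles) <- species
  }
  if (!all(roles %in% c("competitive", "opportunistic", "nondegrader"))) {
    stop("roles must be competitive, opportunistic or nondegrader")
  }
  degraders <- species[order(match(roles, c("competitive", "opportunistic")),
                             species)]
  degraders <- degraders[roles[degraders] != "nondegrader"]
  if (is.null(ec_repertoire)) {
    # deal 2-4 ECs per degrader round-robin: repertoire breadth varies
    # across degraders and every EC receives several transcribers
    ec_repertoire <- list()
    sizes <- rep(c(3, 2, 4), length.out = length(degraders))
    start <- 0
    gal <- c("3.2.1.22", "3.2.1.23")
    for (j in seq_along(degraders)) {
      idx <- (start + seq_len(sizes[j]) - 1) %% length(ecs) + 1
      rep_j <- ecs[unique(idx)]
      if (all(rep_j %in% gal)) {
        # never plant a galactosidase-only degrader: it would be
        # screened out by design
        rep_j <- ecs[unique(c(idx, max(idx) %% length(ecs) + 1))]
      }
      ec_repertoire[[degraders[j]]] <- rep_j
      start <- start + sizes[j]
    }
  }
  empty <- vapply(degraders,
                  function(s) length(ec_repertoire[[s]] %||% character()) == 0,
                  logical(1))
  if (any(empty)) {
    stop("degrader species with empty EC repertoire: ",
         paste(degraders[empty], collapse = ", "))
  }
  structure(
    list(n_samples = n_samples, n_species = n_species,
         n_clusters = n_clusters, within_cluster_rho = within_cluster_rho,
         total_reads_per_sample = total_reads_per_sample,
         species = species, cluster = cluster, roles = roles,
         ec_repertoire = ec_repertoire,
         coupling_strength = coupling_strength,
         suppression_strength = suppression_strength,
         opportunist_baseline = opportunist_baseline,
         expression_offset = expression_offset,
         noise_sd = noise_sd,
         unclassified_fraction = unclassified_fraction,
         gh_ratio = gh_ratio, mu_sd = mu_sd,
         seed = as.integer(seed), catalog = catalog),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(paste0(
    "generator_config: %d samples x %d species, %d clusters (rho %.2f)\n",
    "  roles: %d competitive, %d opportunistic, %d nondegrader; seed %d\n"),
    x$n_samples, x$n_species, x$n_clusters, x$within_cluster_rho,
    sum(x$roles == "competitive"), sum(x$roles == "opportunistic"),
    sum(x$roles == "nondegrader"), x$seed))
  invisible(x)
}

#' Simulate a compositional abundance table with planted clusters
#'
#' Latent per-sample log-abundances are multivariate normal with a
#' block-diagonal correlation structure (`within_cluster_rho` inside each
#' planted cluster, 0 between clusters), shifted by species-specific mean
#' log-abundances. Each sample's latent vector is softmax-closed to
#' proportions and read counts are drawn multinomially at the configured
#' depth, mimicking overdispersed compositional sequencing counts.
#'
#' @param config a [generator_config()].
#' @return list with `abundance` (an [abundance_table()]) and `truth`
#'   (list: `cluster_assignment`, `role`).
#' @export
simulate_abundances <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    n <- config$n_samples
    p <- config$n_species
    mu <- stats::rnorm(p, 0, config$mu_sd)
    rho <- config$within_cluster_rho
    z <- matrix(stats::rnorm(n * p), n, p)
    if (rho > 0) {
      # block-equicorrelated: x_i = sqrt(rho) * shared + sqrt(1-rho) * own
      shared <- matrix(stats::rnorm(n * config$n_clusters), n)
      z <- sqrt(rho) * shared[, config$cluster] + sqrt(1 - rho) * z
    }
    latent <- sweep(z, 2, mu, "+")
    props <- exp(latent)
    props <- props / rowSums(props)
    counts <- t(apply(props, 1, function(pr) {
      stats::rmultinom(1, config$total_reads_per_sample, pr)[, 1]
    }))
    dimnames(counts) <- list(sprintf("S%03d", seq_len(n)), config$species)
    ab <- abundance_table(counts)
    list(abundance = ab,
         truth = list(cluster_assignment = config$cluster,
                      role = config$roles))
  })
}

# Offset rate of a competitive species: cpm per clr unit above the
# expression offset, truncated at zero after noise.
.competitive_rate <- function(clr_vec, config) {
  config$coupling_strength * (clr_vec - config$expression_offset)
}

#' Simulate species-stratified EC transcription
#'
#' Applies the planted transcription regimes to a simulated (or observed)
#' abundance table. For every EC in the configured repertoires:
#' competitive transcribers emit
#' `coupling_strength * (clr - expression_offset)` cpm plus Gaussian
#' noise (truncated at zero); opportunistic transcribers emit
#' `opportunist_baseline / (1 + exp(suppression_strength * (C - mean(C))))`
#' plus noise, where `C` is the per-sample sum of clr abundances of the
#' EC's competitive transcribers; nondegraders emit nothing. Community
#' totals are the species strata plus a small UNCLASSIFIED remainder.
#'
#' @param abund an [abundance_table()].
#' @param config a [generator_config()]; transcription noise uses
#'   `config$seed + 1` so that abundance and transcription draws are
#'   reproducible separately.
#' @return list with `transcription` (a [stratified_table()]) and `truth`
#'   (list with `planted_edges`: data.frame predictor/response/ec/sign,
#'   `role`, `cluster_assignment`).
#' @export
simulate_transcription <- function(abund, config) {
  stopifnot(inherits(abund, "abundance_table"),
            inherits(config, "generator_config"))
  clr <- clr_transform(abund)
  n <- length(abund$sample_ids)
  transcribers <- names(config$ec_repertoire)
  ec_all <- sort(unique(unlist(config$ec_repertoire)))
  with_seed(config$seed + 1L, {
    rows <- list()
    edges <- list()
    for (ec in ec_all) {
      sp_ec <- transcribers[vapply(transcribers, function(s)
        ec %in% config$ec_repertoire[[s]], logical(1))]
      comp <- sp_ec[config$roles[sp_ec] == "competitive"]
      opp <- sp_ec[config$roles[sp_ec] == "opportunistic"]
      cpm <- matrix(0, n, length(sp_ec),
                    dimnames = list(abund$sample_ids, sp_ec))
      C <- if (length(comp)) rowSums(clr[, comp, drop = FALSE]) else
        numeric(n)
      for (s in comp) {
        cpm[, s] <- pmax(0, .competitive_rate(clr[, s], config) +
                           stats::rnorm(n, 0, config$noise_sd))
      }
      supp <- 1 / (1 + exp(config$suppression_strength * (C - mean(C))))
      for (s in opp) {
        cpm[, s] <- pmax(0, config$opportunist_baseline * supp +
                           stats::rnorm(n, 0, config$noise_sd))
      }
      if (length(comp) && length(opp) && config$suppression_strength > 0) {
        edges[[ec]] <- expand.grid(predictor = comp, response = opp,
                                   stringsAsFactors = FALSE)
        edges[[ec]]$ec <- ec
        edges[[ec]]$sign <- "negative"
      }
      sp_sum <- rowSums(cpm)
      # noisy unattributed remainder: contributions vary even for ECs
      # with a lone transcriber
      uncl <- config$unclassified_fraction * sp_sum *
        exp(stats::rnorm(n, 0, 0.25))
      long <- data.frame(
        sample = rep(abund$sample_ids, times = length(sp_ec) + 1),
        ec = ec,
        species = rep(c(sp_ec, UNCLASSIFIED), each = n),
        cpm = c(as.vector(cpm), uncl),
        stringsAsFactors = FALSE
      )
      rows[[ec]] <- long[long$cpm > 0, , drop = FALSE]
    }
    strata <- do.call(rbind, rows)
    if (is.null(strata) || nrow(strata) == 0) {
      strata <- data.frame(sample = character(), ec = character(),
                           species = character(), cpm = numeric(),
                           stringsAsFactors = FALSE)
    }
    mt <- stratified_table(strata)
    list(transcription = mt,
         truth = list(
           planted_edges = if (length(edges)) do.call(rbind, edges) else
             data.frame(predictor = character(), response = character(),
                        ec = character(), sign = character()),
           role = config$roles,
           cluster_assignment = config$cluster))
  })
}

#' Simulate a species-stratified gene (metagenome) table
#'
#' Gene copies scale with organism abundance: every degrader contributes
#' each EC of its repertoire in proportion to its relative abundance
#' whenever it is present in a sample. In addition, each degrader encodes
#' (and transcribes) a planted number of non-catalog glycoside hydrolase
#' ECs proportional to its mucin repertoire size (`gh_ratio`), supporting
#' repertoire-comparison analyses.
#'
#' @param abund an [abundance_table()].
#' @param config a [generator_config()]; uses `config$seed + 2`.
#' @return list with `genes` (a [stratified_table()]), `other_gh`
#'   (data.frame species / n_mucin / n_other_gh ground truth) and
#'   `other_gh_ecs` (named list species -> other-GH EC ids).
#' @export
simulate_gene_content <- function(abund, config) {
  stopifnot(inherits(abund, "abundance_table"),
            inherits(config, "generator_config"))
  transcribers <- names(config$ec_repertoire)
  # pool of plausible non-catalog GH ECs (3.2.1.-)
  pool <- sprintf("3.2.1.%d", c(1:17, 20, 21, 24:48))
  pool <- setdiff(pool, config$catalog$ec_id)
  with_seed(config$seed + 2L, {
    rows <- list()
    gh_truth <- list()
    gh_sets <- list()
    offset <- 0
    for (s in transcribers) {
      n_mucin <- length(config$ec_repertoire[[s]])
      n_other <- max(0, round(config$gh_ratio * n_mucin +
                                stats::rnorm(1, 0, 0.5)))
      n_other <- min(n_other, length(pool))
      other <- pool[(offset + seq_len(n_other) - 1) %% length(pool) + 1]
      offset <- offset + n_other
      gh_sets[[s]] <- other
      gh_truth[[s]] <- data.frame(species = s, n_mucin = n_mucin,
                                  n_other_gh = n_other,
                                  stringsAsFactors = FALSE)
      rel <- abund$rel_abundance[, s]
      present <- rel > 0
      if (!any(present)) next
      for (ec in c(config$ec_repertoire[[s]], other)) {
        rows[[paste(s, ec)]] <- data.frame(
          sample = abund$sample_ids[present], ec = ec, species = s,
          cpm = 10 * rel[present], stringsAsFactors = FALSE)
      }
    }
    strata <- do.call(rbind, rows)
    if (is.null(strata)) {
      strata <- data.frame(sample = character(), ec = character(),
                           species = character(), cpm = numeric())
    }
    list(genes = stratified_table(strata),
         other_gh = do.call(rbind, c(gh_truth, list(make.row.names = FALSE))),
         other_gh_ecs = gh_sets)
  })
}

#' Simulate a full paired metagenome/metatranscriptome community
#'
#' Convenience wrapper running [simulate_abundances()],
#' [simulate_gene_content()] and [simulate_transcription()] under one
#' configuration.
#'
#' @param config a [generator_config()].
#' @return list with `abundance`, `genes`, `transcription`, `truth`
#'   (clusters, roles, planted edges, other-GH repertoire sizes).
#' @export
simulate_community <- function(config) {
  ab <- simulate_abundances(config)
  mg <- simulate_gene_content(ab$abundance, config)
  mt <- simulate_transcription(ab$abundance, config)
  # Other-GH ECs are transcribed alongside mucin ECs (same planted ratio).
  list(abundance = ab$abundance,
       genes = mg$genes,
       transcription = add_other_gh_transcription(mt$transcription,
                                                  ab$abundance, mg, config),
       truth = c(mt$truth, list(other_gh = mg$other_gh,
                                other_gh_ecs = mg$other_gh_ecs)))
}

# Degraders transcribe their other-GH ECs proportionally to abundance, so
# transcribed repertoires mirror encoded ones.
add_other_gh_transcription <- function(mt, abund, mg, config) {
  rows <- list()
  for (s in names(mg$other_gh_ecs)) {
    rel <- abund$rel_abundance[, s]
    present <- rel > 0
    if (!any(present)) next
    for (ec in mg$other_gh_ecs[[s]]) {
      rows[[paste(s, ec)]] <- data.frame(
        sample = abund$sample_ids[present], ec = ec, species = s,
        cpm = rel[present], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(mt)
  stratified_table(rbind(mt$strata, do.call(rbind, rows)))
}

#' Write a fixture bundle of generated community data
#'
#' Emits per-sample abundance profiles, stratified gene and transcription
#' tables, the EC catalog, ground-truth tables (roles, clusters, planted
#' edges) and a manifest with md5 checksums.
#'
#' @param config a [generator_config()].
#' @param outdir output directory.
#' @return invisibly, the manifest data.frame (`file`, `md5`).
#' @export
write_fixture_bundle <- function(config, outdir) {
  sim <- simulate_community(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  paths <- write_abundance_profiles(sim$abundance, outdir)
  p_mg <- file.path(outdir, "genefamilies_ec.tsv")
  p_mt <- file.path(outdir, "transcripts_ec.tsv")
  write_stratified_ec_table(sim$genes, p_mg)
  write_stratified_ec_table(sim$transcription, p_mt)
  p_cat <- file.path(outdir, "ec_catalog.tsv")
  utils::write.table(as.data.frame(config$catalog), p_cat, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  p_truth <- file.path(outdir, "ground_truth_species.tsv")
  utils::write.table(
    data.frame(species = config$species,
               cluster = unname(config$cluster),
               role = unname(config$roles)),
    p_truth, sep = "\t", quote = FALSE, row.names = FALSE)
  p_edges <- file.path(outdir, "ground_truth_edges.tsv")
  utils::write.table(sim$truth$planted_edges, p_edges, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c(unname(paths), p_mg, p_mt, p_cat, p_truth, p_edges)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(outdir, "MANIFEST.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
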