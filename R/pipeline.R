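#' Assemble a pipeline run configuration
#'
#' Collects the input sources and every analysis threshold into one
#' validated object. Inputs are either file paths (per-sample abundance
#' profiles plus stratified gene/transcript tables) or a
#' [generator_config()] to simulate a community.
#'
#' @param profiles character vector of per-sample abundance profile
#'   paths (ignored when `generator` is supplied).
#' @param genes_path,transcripts_path stratified EC tables (metagenome
#'   and metatranscriptome).
#' @param generator optional [generator_config()]; when present the
#'   community is simulated instead of read from files.
#' @param catalog_path EC catalog path (`NULL`: shipped default).
#' @param outdir output directory for artifacts.
#' @param min_prevalence per-(EC, species) transcription prevalence
#'   retention threshold (default 0.10, `>=`).
#' @param ec_prevalence EC-level prevalence threshold (default 0.05,
#'   strict `>`).
#' @param min_rho co-occurrence edge retention threshold (default 0.2).
#' @param ci_level permutation-null central interval (default 0.99).
#' @param n_reps permutation replicates (default 1000; < 100 rejected).
#' @param alpha linear-model significance level (default 0.05).
#' @param competitive_threshold continuum classification threshold on
#'   the median adjusted R-squared (default 0.2).
#' @param min_present_samples species presence filter for the
#'   co-occurrence network (default 20).
#' @param pseudocount clr pseudocount (default 1).
#' @param seed integer seed governing the permutation null (and the
#'   generator, if its own seed is `NULL`).
#' @return a `run_config` list.
#' @export
run_config <- function(profiles = NULL, genes_path = NULL,
                       transcripts_path = NULL, generator = NULL,
                       catalog_path = NULL, outdir = NULL,
                       min_prevalence = 0.10, ec_prevalence = 0.05,
                       min_rho = 0.2, ci_level = 0.99, n_reps = 1000,
                       alpha = 0.05, competitive_threshold = 0.2,
                       min_present_samples = 20, pseudocount = 1,
                       seed = 1L) {
  if (is.null(generator) &&
      (is.null(profiles) || is.null(transcripts_path))) {
    stop("either a generator config or input paths ",
         "(profiles + transcripts_path) are required")
  }
  if (n_reps < 100) stop("n_reps must be >= 100")
  stopifnot(min_prevalence >= 0, min_prevalence <= 1,
            ec_prevalence >= 0, ec_prevalence <= 1,
            min_rho >= 0, min_rho <= 1,
            ci_level > 0, ci_level < 1,
            alpha > 0, alpha < 1,
            pseudocount >= 0, min_present_samples >= 3)
  structure(
    list(profiles = profiles, genes_path = genes_path,
         transcripts_path = transcripts_path, generator = generator,
         catalog_path = catalog_path, outdir = outdir,
         min_prevalence = min_prevalence, ec_prevalence = ec_prevalence,
         min_rho = min_rho, ci_level = ci_level, n_reps = n_reps,
         alpha = alpha, competitive_threshold = competitive_threshold,
         min_present_samples = min_present_samples,
         pseudocount = pseudocount, seed = as.integer(seed)),
    class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; a `generator`
#' mapping is forwarded to [generator_config()].
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$generator)) {
    y$generator <- do.call(generator_config, y$generator)
  }
  do.call(run_config, y)
}

#' Run the full degrader-ecology pipeline
#'
#' Executes every stage in order: input loading (or simulation), clr
#' transform, EC prevalence summary, the degrader filter cascade, the
#' permutation-calibrated co-occurrence network with greedy-modularity
#' clustering, per-EC contribution and abundance-driven fits, the
#' response-predictor networks, the cross-EC consensus network and the
#' competitive-opportunistic continuum summary. All artifacts are
#' written as TSV under `config$outdir` (when set) and the full results
#' are returned.
#'
#' @param config a [run_config()].
#' @return a `pipeline_run`: list with `results` (all stage outputs) and
#'   `report` (a `run_report` with per-stage counts, filter attrition,
#'   warnings, config hash and seed).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  warnings_seen <- character()
  note <- function(w) warnings_seen <<- c(warnings_seen, w)
  with_notes <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      note(conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }

  catalog <- load_ec_catalog(config$catalog_path)
  if (!is.null(config$generator)) {
    sim <- simulate_community(config$generator)
    abund <- sim$abundance
    mg <- sim$genes
    mt <- sim$transcription
    truth <- sim$truth
  } else {
    abund <- with_notes(read_abundance_profiles(config$profiles))
    mg <- if (!is.null(config$genes_path)) {
      with_notes(read_stratified_ec_table(config$genes_path))
    } else NULL
    mt <- with_notes(read_stratified_ec_table(config$transcripts_path))
    truth <- NULL
  }
  clr <- clr_transform(abund, config$pseudocount)

  ec_summary <- ec_prevalence(mt, catalog, config$ec_prevalence)
  calls <- with_notes(call_degraders(mg, mt, catalog,
                                     config$min_prevalence))

  net <- with_notes(cooccurrence_network(
    abund, calls$prevalent_versatile,
    min_present_samples = config$min_present_samples,
    n_reps = config$n_reps, ci_level = config$ci_level,
    seed = config$seed, min_rho = config$min_rho,
    pseudocount = config$pseudocount))

  contrib <- contributions(mt, catalog)
  pairs <- prevalent_pairs(mt, catalog, calls$prevalent_versatile,
                           config$min_prevalence)
  fits <- abundance_driven_fits(contrib, clr, pairs,
                                alpha = config$alpha)
  rp <- response_predictor_networks(contrib, clr, pairs,
                                    alpha = config$alpha)
  summary <- ecology_summary(fits, rp$edges, rp$eligible,
                             config$competitive_threshold)

  attrition <- data.frame(
    stage = c("species_in_profiles", "encoders", "transcribers",
              "versatile", "prevalent_versatile"),
    n = c(length(abund$species_ids), length(calls$encoders),
          length(calls$transcribers), length(calls$versatile),
          length(calls$prevalent_versatile)))
  report <- structure(
    list(counts = c(
           n_samples = length(abund$sample_ids),
           n_species = length(abund$species_ids),
           n_ecs_detected = sum(ec_summary$prevalence > 0),
           n_ecs_prevalent = sum(ec_summary$prevalent),
           n_network_nodes = nrow(net$nodes),
           n_network_edges = nrow(net$edges),
           n_clusters = length(unique(stats::na.omit(net$nodes$cluster))),
           n_abundance_fits = sum(!fits$skipped),
           n_rp_edges = nrow(rp$edges),
           n_consensus_edges = nrow(rp$consensus)),
         attrition = attrition,
         warnings = warnings_seen,
         # the hash fingerprints the analysis parameters, not where the
         # artifacts land
         config_hash = object_hash(unclass(config)[
           setdiff(names(config), "outdir")]),
         seed = config$seed,
         version = as.character(utils::packageVersion("glycoguild"))),
    class = "run_report")

  results <- list(abundance = abund, genes = mg, transcription = mt,
                  clr = clr, catalog = catalog, ec_summary = ec_summary,
                  calls = calls, network = net, contributions = contrib,
                  abundance_fits = fits, rp = rp,
                  ecology = summary, truth = truth)
  if (!is.null(config$outdir)) {
    write_pipeline_artifacts(results, report, config$outdir)
  }
  structure(list(results = results, report = report),
            class = "pipeline_run")
}

write_pipeline_artifacts <- function(res, report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name, comment) {
    write_tsv_artifact(df, file.path(outdir, name),
                       paste0(comment, " | config ", report$config_hash))
  }
  w(res$ec_summary, "ec_summary.tsv", "per-EC prevalence and abundance")
  calls_df <- data.frame(
    species = res$calls$transcribers,
    tier = ifelse(res$calls$transcribers %in% res$calls$prevalent_versatile,
                  "prevalent_versatile",
                  ifelse(res$calls$transcribers %in% res$calls$versatile,
                         "versatile", "transcriber")),
    transcribed_ecs = vapply(
      res$calls$transcribed_ecs[res$calls$transcribers],
      paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE)
  w(calls_df, "degrader_calls.tsv", "degrader filter cascade calls")
  w(res$calls$prevalence, "transcription_prevalence.tsv",
    "per-(EC, species) transcription prevalence")
  export_network(res$network, outdir)
  w(res$abundance_fits, "abundance_fits.tsv",
    "abundance-driven transcription fits")
  w(res$rp$edges, "rp_edges.tsv", "response-predictor edges")
  w(res$rp$consensus, "consensus_edges.tsv", "cross-EC consensus edges")
  w(res$ecology$species, "ecology_summary.tsv",
    "competitive-opportunistic continuum")
  trends <- do.call(rbind, lapply(names(res$ecology$trends), function(n) {
    t <- res$ecology$trends[[n]]
    data.frame(trend = n, slope = t$slope, model_p = t$model_p,
               adj_r2 = t$adj_r2, stringsAsFactors = FALSE)
  }))
  w(trends, "trend_fits.tsv", "continuum trend fits")
  w(report$attrition, "attrition.tsv", "filter cascade attrition")
  jsonlite::write_json(
    list(counts = as.list(report$counts),
         warnings = report$warnings, config_hash = report$config_hash,
         seed = report$seed, version = report$version),
    file.path(outdir, "run_report.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("pipeline run report (glycoguild", x$version, ")\n")
  cat(sprintf("  seed %d, config %s\n", x$seed, x$config_hash))
  for (n in names(x$counts)) {
    cat(sprintf("  %-22s %d\n", n, x$counts[[n]]))
  }
  cat("  filter attrition:",
      paste(sprintf("%s=%d", x$attrition$stage, x$attrition$n),
            collapse = " -> "), "\n")
  if (length(x$warnings)) {
    cat(sprintf("  %d warning(s), first: %s\n", length(x$warnings),
                x$warnings[1]))
  }
  invisible(x)
}

#' @export
print.pipeline_run <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' @export
summary.pipeline_run <- function(object, ...) {
  print(object$results$ecology)
  invisible(object$results$ecology)
}
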