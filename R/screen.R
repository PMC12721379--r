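#' Per-EC detection prevalence and abundance summary
#'
#' For every catalog EC, computes the fraction of samples in which the
#' EC's community total is detectable (> 0 cpm) and the mean cpm across
#' all samples. ECs with prevalence at or below `ec_prevalence` (strict
#' "> 5%" semantics by default) are flagged non-prevalent; catalog ECs
#' absent from the table get prevalence 0.
#'
#' @param table a [stratified_table()].
#' @param catalog an EC catalog ([load_ec_catalog()]).
#' @param ec_prevalence prevalence threshold; an EC is prevalent only if
#'   its prevalence is strictly greater (default 0.05).
#' @return data.frame with `ec_id`, `name`, `prevalence`, `mean_cpm`,
#'   `n_species` (species with any stratum cpm > 0), `prevalent`.
#' @export
ec_prevalence <- function(table, catalog, ec_prevalence = 0.05) {
  stopifnot(inherits(table, "stratified_table"))
  if (length(table$sample_ids) == 0) stop("empty stratified table")
  n <- length(table$sample_ids)
  tot <- community_totals(table, intersect(catalog$ec_id, table$ec_ids))
  out <- data.frame(ec_id = catalog$ec_id, name = catalog$name,
                    prevalence = 0, mean_cpm = 0, n_species = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    ec <- out$ec_id[i]
    if (ec %in% colnames(tot)) {
      out$prevalence[i] <- mean(tot[, ec] > 0)
      out$mean_cpm[i] <- mean(tot[, ec])
      sp <- table$strata$species[table$strata$ec == ec]
      out$n_species[i] <- length(setdiff(unique(sp), UNCLASSIFIED))
    }
  }
  out$prevalent <- out$prevalence > ec_prevalence
  out
}

#' Per-(EC, species) transcription prevalence
#'
#' Prevalence is defined relative to the samples in which an EC is
#' transcribed at all: the number of samples where the species' stratum
#' is detectable divided by the number of samples where the EC's
#' community total is detectable. The denominator depends only on
#' community totals, never on the focal species.
#'
#' @param table a [stratified_table()].
#' @param ecs EC ids to evaluate (default: all in the table).
#' @return data.frame `ec`, `species`, `n_samples_ec_transcribed`,
#'   `n_samples_species_transcribes`, `prevalence` (NA when the EC is
#'   never transcribed).
#' @export
transcription_prevalence <- function(table, ecs = NULL) {
  stopifnot(inherits(table, "stratified_table"))
  ecs <- ecs %||% table$ec_ids
  tot <- community_totals(table, intersect(ecs, table$ec_ids))
  rows <- list()
  for (ec in ecs) {
    denom <- if (ec %in% colnames(tot)) sum(tot[, ec] > 0) else 0L
    s <- table$strata[table$strata$ec == ec &
                        table$strata$species != UNCLASSIFIED, , drop = FALSE]
    if (nrow(s) == 0) next
    cnt <- tapply(s$cpm > 0, s$species, sum)
    rows[[ec]] <- data.frame(
      ec = ec, species = names(cnt),
      n_samples_ec_transcribed = denom,
      n_samples_species_transcribes = as.integer(cnt),
      prevalence = if (denom > 0) as.numeric(cnt) / denom else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(ec = character(), species = character(),
                      n_samples_ec_transcribed = integer(),
                      n_samples_species_transcribes = integer(),
                      prevalence = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Identify mucosal glycan degraders via the filter cascade
#'
#' Starting from the species encoding any active catalog EC (metagenome)
#' and the species transcribing any (metatranscriptome), the cascade (i)
#' removes species whose transcribed ECs are a subset of the
#' galactosidases (3.2.1.22 / 3.2.1.23; galactose is too widely available
#' for these alone to indicate mucin use), (ii) removes species
#' transcribing exactly one catalog EC (not versatile), and (iii) keeps
#' species whose transcription prevalence reaches `min_prevalence` for at
#' least one EC (prevalence is relative to samples where that EC is
#' transcribed at all). The versatility count includes the galactosidases
#' themselves: a species transcribing beta-galactosidase plus a sialidase
#' is versatile.
#'
#' @param mg metagenome (gene) [stratified_table()], or `NULL` to skip
#'   encoder calls.
#' @param mt metatranscriptome (transcript) [stratified_table()].
#' @param catalog an EC catalog.
#' @param min_prevalence retention threshold, `>=` semantics
#'   (default 0.10).
#' @param count_excluded_in_versatility if `FALSE`, the galactosidase ECs
#'   do not count towards the > 1 EC versatility requirement.
#' @return a `degrader_calls` object: list with `encoders`,
#'   `transcribers`, `versatile`, `prevalent_versatile` (character
#'   vectors), `transcribed_ecs` (named list), `prevalence` (per-EC,
#'   species table restricted to transcribers), `mean_contribution`
#'   (per-species, per-EC mean % contribution over samples where the EC
#'   is transcribed), and the thresholds used.
#' @export
call_degraders <- function(mg, mt, catalog, min_prevalence = 0.10,
                           count_excluded_in_versatility = TRUE) {
  stopifnot(inherits(mt, "stratified_table"))
  ecs <- active_ecs(catalog)
  excl <- intersect(excluded_ecs(catalog), ecs)

  species_with_signal <- function(tab) {
    if (is.null(tab)) return(character())
    s <- tab$strata
    sort(unique(s$species[s$ec %in% ecs & s$species != UNCLASSIFIED &
                            s$cpm > 0]))
  }
  encoders <- species_with_signal(mg)
  transcribers <- species_with_signal(mt)
  if (length(transcribers) == 0) {
    warning("no species transcribe any catalog EC; empty call set")
  }
  s <- mt$strata[mt$strata$ec %in% ecs &
                   mt$strata$species %in% transcribers, , drop = FALSE]
  transcribed_ecs <- lapply(
    stats::setNames(transcribers, transcribers),
    function(sp) sort(unique(s$ec[s$species == sp & s$cpm > 0])))

  galactosidase_only <- vapply(transcribed_ecs, function(e)
    length(e) > 0 && all(e %in% excl), logical(1))
  versatile <- transcribers[!galactosidase_only[transcribers]]
  n_ecs <- vapply(transcribed_ecs[versatile], function(e) {
    if (count_excluded_in_versatility) length(e) else
      length(setdiff(e, excl))
  }, integer(1))
  versatile <- versatile[n_ecs > 1]

  prev <- transcription_prevalence(mt, ecs)
  prev <- prev[prev$species %in% transcribers, , drop = FALSE]
  ok <- prev$species %in% versatile & !is.na(prev$prevalence) &
    prev$prevalence >= min_prevalence
  prevalent_versatile <- sort(unique(prev$species[ok]))

  contrib <- contributions(mt, catalog)
  mc <- if (nrow(contrib)) {
    agg <- stats::aggregate(contribution ~ species + ec, data = contrib,
                            FUN = mean)
    agg[agg$species != UNCLASSIFIED, , drop = FALSE]
  } else contrib

  structure(
    list(encoders = encoders, transcribers = transcribers,
         versatile = sort(versatile),
         prevalent_versatile = prevalent_versatile,
         transcribed_ecs = transcribed_ecs,
         prevalence = prev, mean_contribution = mc,
         min_prevalence = min_prevalence),
    class = "degrader_calls")
}

#' @export
print.degrader_calls <- function(x, ...) {
  cat(sprintf(paste0(
    "degrader_calls: %d encoding, %d transcribing, %d versatile,\n",
    "  %d prevalently transcribing (prevalence >= %.2f)\n"),
    length(x$encoders), length(x$transcribers), length(x$versatile),
    length(x$prevalent_versatile), x$min_prevalence))
  if (length(x$prevalent_versatile)) {
    cat("  prevalent versatile degraders:\n")
    cat(strwrap(paste(x$prevalent_versatile, collapse = ", "),
                indent = 4, exdent = 4), sep = "\n")
  }
  invisible(x)
}

#' Compare mucin-degradation and overall glycoside hydrolase repertoires
#'
#' Counts, per species, the distinct catalog (mucin) ECs and the distinct
#' other glycoside hydrolase ECs (pattern `3.2.1.-`, minus catalog
#' members) it encodes and transcribes, and fits the linear trend of
#' other-GH count on mucin count for each table.
#'
#' @param mg metagenome [stratified_table()].
#' @param mt metatranscriptome [stratified_table()].
#' @param catalog an EC catalog.
#' @param species restrict to these species (default: all with any
#'   catalog EC in the respective table).
#' @return list with `counts` (data.frame species / table / n_mucin_ecs /
#'   n_other_gh_ecs) and `trends` (per table: slope, intercept,
#'   adjusted R^2, model p; NA when undefined).
#' @export
gh_repertoire_comparison <- function(mg, mt, catalog, species = NULL) {
  ecs <- active_ecs(catalog)
  one <- function(tab, label) {
    s <- tab$strata[tab$strata$species != UNCLASSIFIED & tab$strata$cpm > 0, ]
    is_gh <- grepl("^3\\.2\\.1\\.", s$ec)
    sp <- species %||% sort(unique(s$species[s$ec %in% ecs]))
    res <- data.frame(species = sp, table = label, n_mucin_ecs = 0L,
                      n_other_gh_ecs = 0L, stringsAsFactors = FALSE)
    for (i in seq_along(sp)) {
      e <- unique(s$ec[s$species == sp[i]])
      res$n_mucin_ecs[i] <- length(intersect(e, ecs))
      res$n_other_gh_ecs[i] <-
        length(setdiff(e[grepl("^3\\.2\\.1\\.", e)], catalog$ec_id))
    }
    res
  }
  counts <- rbind(one(mg, "metagenome"), one(mt, "metatranscriptome"))
  trends <- lapply(split(counts, counts$table), function(d) {
    if (nrow(d) < 3 || stats::var(d$n_mucin_ecs) == 0 ||
        all(d$n_other_gh_ecs == 0)) {
      return(list(slope = NA_real_, intercept = NA_real_,
                  adj_r2 = NA_real_, model_p = NA_real_,
                  defined = FALSE))
    }
    fit <- stats::lm(n_other_gh_ecs ~ n_mucin_ecs, data = d)
    sm <- summary(fit)
    f <- sm$fstatistic
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         adj_r2 = sm$adj.r.squared,
         model_p = unname(stats::pf(f[1], f[2], f[3], lower.tail = FALSE)),
         defined = TRUE)
  })
  list(counts = counts, trends = trends)
}
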