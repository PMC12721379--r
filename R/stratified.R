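#' Construct a species-stratified functional table
#'
#' Holds copies-per-million (cpm) values for enzyme-commission (EC)
#' features split by contributing species, plus per-(sample, EC) community
#' totals. The `UNCLASSIFIED` stratum collects cpm not attributed to any
#' species; species strata plus the unclassified stratum never exceed the
#' community total.
#'
#' @param strata data.frame with columns `sample`, `ec`, `species`, `cpm`
#'   (species may be `"UNCLASSIFIED"`); zero-cpm rows are dropped.
#' @param totals data.frame with columns `sample`, `ec`, `cpm`; if `NULL`,
#'   totals are imputed as the sum of strata.
#' @param tol consistency tolerance for strata exceeding totals.
#' @return a `stratified_table`: list with `strata`, `totals`,
#'   `sample_ids`, `ec_ids`, `species_ids` (excluding UNCLASSIFIED).
#' @export
stratified_table <- function(strata, totals = NULL, tol = 1e-6) {
  need <- c("sample", "ec", "species", "cpm")
  if (!all(need %in% names(strata))) {
    stop("strata needs columns: ", paste(need, collapse = ", "))
  }
  strata$cpm <- as.numeric(strata$cpm)
  if (any(!is.finite(strata$cpm)) || any(strata$cpm < 0)) {
    stop("cpm values must be finite and nonnegative")
  }
  bad_ec <- !ec_id_ok(strata$ec)
  if (any(bad_ec)) {
    stop("malformed EC id(s): ",
         paste(unique(strata$ec[bad_ec]), collapse = ", "))
  }
  strata <- strata[!is_zero(strata$cpm), need, drop = FALSE]
  key <- paste(strata$sample, strata$ec, sep = "\t")
  strat_sum <- tapply(strata$cpm, key, sum)
  if (is.null(totals)) {
    if (length(strat_sum) == 0) {
      totals <- data.frame(sample = character(), ec = character(),
                           cpm = numeric(), stringsAsFactors = FALSE)
    } else {
      parts <- do.call(rbind,
                       strsplit(names(strat_sum), "\t", fixed = TRUE))
      totals <- data.frame(sample = parts[, 1], ec = parts[, 2],
                           cpm = as.numeric(strat_sum),
                           stringsAsFactors = FALSE)
    }
  } else {
    totals <- totals[, c("sample", "ec", "cpm")]
    totals$cpm <- as.numeric(totals$cpm)
    tkey <- paste(totals$sample, totals$ec, sep = "\t")
    ssum <- strat_sum[tkey]
    ssum[is.na(ssum)] <- 0
    over <- ssum > totals$cpm + tol
    if (any(over)) {
      stop("strata exceed community total for: ",
           paste(utils::head(tkey[over], 5), collapse = "; "))
    }
    # (sample, ec) pairs with strata but no explicit total: impute.
    miss <- setdiff(names(strat_sum), tkey)
    if (length(miss)) {
      warning(length(miss),
              " (sample, EC) pair(s) lack a community-total row; ",
              "imputed as the sum of strata")
      parts <- do.call(rbind, strsplit(miss, "\t", fixed = TRUE))
      totals <- rbind(totals,
                      data.frame(sample = parts[, 1], ec = parts[, 2],
                                 cpm = as.numeric(strat_sum[miss]),
                                 stringsAsFactors = FALSE))
    }
  }
  totals <- totals[!is_zero(totals$cpm), , drop = FALSE]
  rownames(strata) <- rownames(totals) <- NULL
  structure(
    list(strata = strata, totals = totals,
         sample_ids = sort(unique(c(strata$sample, totals$sample))),
         ec_ids = sort(unique(c(strata$ec, totals$ec))),
         species_ids = sort(setdiff(unique(strata$species), UNCLASSIFIED))),
    class = "stratified_table"
  )
}

#' @export
print.stratified_table <- function(x, ...) {
  cat(sprintf(
    "stratified_table: %d samples, %d ECs, %d species (+%s), %d strata\n",
    length(x$sample_ids), length(x$ec_ids), length(x$species_ids),
    UNCLASSIFIED, nrow(x$strata)))
  invisible(x)
}

#' Community totals of a stratified table
#'
#' @param x a [stratified_table()].
#' @param ecs optional EC subset.
#' @return matrix samples x ECs of community-total cpm (0 where absent).
#' @export
community_totals <- function(x, ecs = NULL) {
  stopifnot(inherits(x, "stratified_table"))
  ecs <- ecs %||% x$ec_ids
  m <- matrix(0, length(x$sample_ids), length(ecs),
              dimnames = list(x$sample_ids, ecs))
  t <- x$totals[x$totals$ec %in% ecs, , drop = FALSE]
  if (nrow(t)) m[cbind(t$sample, t$ec)] <- t$cpm
  m
}

# cpm of one stratum as a samples x species matrix for a given EC.
stratum_matrix <- function(x, ec, species = NULL) {
  species <- species %||% x$species_ids
  m <- matrix(0, length(x$sample_ids), length(species),
              dimnames = list(x$sample_ids, species))
  s <- x$strata[x$strata$ec == ec & x$strata$species %in% species, ,
                drop = FALSE]
  if (nrow(s)) m[cbind(s$sample, s$species)] <- s$cpm
  m
}

#' Read a HUMAnN-style stratified EC table
#'
#' Parses the `humann_regroup_table` output convention: a `# Gene Family`
#' feature column and one numeric column per sample; bare `EC` rows are
#' community totals, `EC|...s__Species` rows are species strata and
#' `EC|unclassified` rows map to the `UNCLASSIFIED` stratum. `UNMAPPED`/
#' `UNGROUPED` rows are ignored. A missing bare-EC row is imputed as the
#' sum of its strata (with a warning).
#'
#' @param path TSV file path.
#' @param dialect currently only `"humann"`.
#' @return a [stratified_table()].
#' @export
read_stratified_ec_table <- function(path, dialect = "humann") {
  dialect <- match.arg(dialect)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("malformed stratified table ", path,
                         " (line 1): need a feature and >=1 sample column")
  feature <- df[[1]]
  samples <- sub("_Abundance(-RPKs)?$", "", names(df)[-1])
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  colnames(vals) <- samples
  keep <- !grepl("^(UNMAPPED|UNGROUPED|UNINTEGRATED)", feature)
  feature <- feature[keep]
  vals <- vals[keep, , drop = FALSE]
  ec <- sub("[|:].*$", "", feature)
  stratum <- ifelse(grepl("\\|", feature),
                    sub("^[^|]*\\|", "", feature), NA_character_)
  species <- ifelse(is.na(stratum), NA_character_,
                    ifelse(grepl("unclassified", stratum, ignore.case = TRUE),
                           UNCLASSIFIED,
                           sub("^.*s__", "", stratum)))
  long <- data.frame(
    sample = rep(samples, each = length(feature)),
    ec = rep(ec, times = length(samples)),
    species = rep(species, times = length(samples)),
    cpm = as.vector(vals),
    stringsAsFactors = FALSE
  )
  strata <- long[!is.na(long$species), c("sample", "ec", "species", "cpm")]
  totals <- long[is.na(long$species), c("sample", "ec", "cpm")]
  stratified_table(strata, if (nrow(totals)) totals else NULL)
}

#' Write a stratified table in the HUMAnN-style dialect
#'
#' @param x a [stratified_table()].
#' @param path output TSV path.
#' @param genus_prefix genus segment used when rebuilding `|g__.s__` row
#'   names for species without one.
#' @return invisibly, `path`.
#' @export
write_stratified_ec_table <- function(x, path, genus_prefix = "g__Synthetic") {
  stopifnot(inherits(x, "stratified_table"))
  feat_total <- unique(x$totals$ec)
  strat_name <- function(ec, sp) {
    ifelse(sp == UNCLASSIFIED, paste0(ec, "|unclassified"),
           paste0(ec, "|", genus_prefix, ".s__", sp))
  }
  feat_strat <- unique(strat_name(x$strata$ec, x$strata$species))
  features <- sort(c(feat_total, feat_strat))
  m <- matrix(0, length(features), length(x$sample_ids),
              dimnames = list(features, x$sample_ids))
  m[cbind(x$totals$ec, x$totals$sample)] <- x$totals$cpm
  m[cbind(strat_name(x$strata$ec, x$strata$species), x$strata$sample)] <-
    x$strata$cpm
  out <- data.frame(`# Gene Family` = features, m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
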