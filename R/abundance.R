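#' Construct a species abundance table
#'
#' Holds, per sample and species, the estimated read counts and the
#' relative abundances (%) from a taxonomic profiler. Rows are samples,
#' columns are species. Relative-abundance rows may sum to less than 100
#' (an unclassified fraction is permitted) but never more.
#'
#' @param read_counts numeric matrix (samples x species) of estimated read
#'   counts, with sample and species dimnames.
#' @param rel_abundance numeric matrix of the same shape, in percent. If
#'   `NULL`, computed by closing `read_counts` to 100 per sample.
#' @return an `abundance_table`: list with `sample_ids`, `species_ids`,
#'   `read_counts`, `rel_abundance`.
#' @export
abundance_table <- function(read_counts, rel_abundance = NULL) {
  read_counts <- as.matrix(read_counts)
  if ((nrow(read_counts) > 0 && is.null(rownames(read_counts))) ||
      (ncol(read_counts) > 0 && is.null(colnames(read_counts)))) {
    stop("read_counts must carry sample (row) and species (column) names")
  }
  if (is.null(rownames(read_counts))) rownames(read_counts) <- character()
  if (is.null(colnames(read_counts))) colnames(read_counts) <- character()
  if (anyDuplicated(rownames(read_counts))) {
    stop("duplicate sample identifiers")
  }
  if (anyDuplicated(colnames(read_counts))) {
    stop("duplicate species identifiers")
  }
  if (any(!is.finite(read_counts)) || any(read_counts < 0)) {
    stop("read counts must be finite and nonnegative")
  }
  if (is.null(rel_abundance)) {
    rs <- rowSums(read_counts)
    rel_abundance <- 100 * read_counts / ifelse(rs > 0, rs, 1)
  }
  rel_abundance <- as.matrix(rel_abundance)
  if (!identical(dim(rel_abundance), dim(read_counts))) {
    stop("rel_abundance and read_counts dimensions differ")
  }
  bad <- rowSums(rel_abundance) > 100 + 1e-6
  if (any(bad)) {
    stop("relative abundances exceed 100% in sample(s): ",
         paste(rownames(read_counts)[bad], collapse = ", "))
  }
  structure(
    list(sample_ids = rownames(read_counts),
         species_ids = colnames(read_counts),
         read_counts = read_counts,
         rel_abundance = rel_abundance),
    class = "abundance_table"
  )
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d species\n",
              length(x$sample_ids), length(x$species_ids)))
  cat(sprintf("  total estimated reads: %.3g (median %.3g per sample)\n",
              sum(x$read_counts), stats::median(rowSums(x$read_counts))))
  invisible(x)
}

# Regex identifying species-level clades in profiler output: a terminal
# "s__" segment with no strain ("t__") refinement.
.SPECIES_CLADE_RE <- "(^|\\|)s__[^|]+$"

#' Read per-sample taxonomic profiles into one abundance table
#'
#' Parses MetaPhlAn-style per-sample TSV profiles carrying clade name,
#' relative abundance and estimated read count columns (the
#' `rel_ab_w_read_stats` output convention), restricts them to
#' species-level clades, and merges them into a single table. Species
#' absent from a sample get zero in both matrices.
#'
#' @param paths character vector of profile files, one per sample.
#' @param sample_ids sample identifiers; defaults to file base names
#'   without extension and without a trailing `_profile` suffix.
#' @param dialect currently only `"metaphlan"`.
#' @param species_regex regex selecting species-level clade rows; the
#'   default keeps terminal `s__` clades and drops strain-level rows.
#' @return an [abundance_table()].
#' @export
read_abundance_profiles <- function(paths,
                                    sample_ids = NULL,
                                    dialect = "metaphlan",
                                    species_regex = .SPECIES_CLADE_RE) {
  dialect <- match.arg(dialect)
  if (is.null(sample_ids)) {
    sample_ids <- sub("_profile$", "", sub("\\.[^.]*$", "", basename(paths)))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  per_sample <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    per_sample[[i]] <- parse_metaphlan_profile(paths[i], species_regex)
    if (nrow(per_sample[[i]]) == 0) {
      warning("no species-level rows in profile: ", paths[i])
    }
  }
  species <- sort(unique(unlist(lapply(per_sample, function(d) d$species))))
  counts <- matrix(0, length(paths), length(species),
                   dimnames = list(sample_ids, species))
  rel <- counts
  for (i in seq_along(per_sample)) {
    d <- per_sample[[i]]
    if (nrow(d)) {
      counts[i, d$species] <- d$reads
      rel[i, d$species] <- d$rel_ab
    }
  }
  out <- abundance_table(counts, rel)
  attr(out, "provenance") <- data.frame(sample_id = sample_ids,
                                        file = paths,
                                        stringsAsFactors = FALSE)
  out
}

parse_metaphlan_profile <- function(path, species_regex) {
  df <- tryCatch(
    utils::read.delim(path, comment.char = "#", check.names = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse profile ", path, ": ",
                             conditionMessage(e))
  )
  cols <- names(df)
  clade_col <- grep("clade_name|^#?clade", cols, value = TRUE)[1]
  rel_col <- grep("relative_abundance", cols, value = TRUE)[1]
  reads_col <- grep("estimated_number_of_reads", cols, value = TRUE)[1]
  if (is.na(clade_col) || is.na(rel_col) || is.na(reads_col)) {
    stop("malformed profile header in ", path,
         " (line 1): need clade_name, relative_abundance and ",
         "estimated_number_of_reads_from_the_clade columns")
  }
  keep <- grepl(species_regex, df[[clade_col]])
  d <- df[keep, , drop = FALSE]
  species <- sub("^.*s__", "", d[[clade_col]])
  data.frame(species = species,
             rel_ab = as.numeric(d[[rel_col]]),
             reads = as.numeric(d[[reads_col]]),
             stringsAsFactors = FALSE)
}

#' Write an abundance table as per-sample profiles
#'
#' Inverse of [read_abundance_profiles()]: one MetaPhlAn-style TSV per
#' sample (`<sample>_profile.tsv`), species rows only.
#'
#' @param x an [abundance_table()].
#' @param outdir output directory (created if needed).
#' @param suffix file-name suffix before the extension.
#' @return invisibly, the written file paths named by sample id.
#' @export
write_abundance_profiles <- function(x, outdir, suffix = "_profile") {
  stopifnot(inherits(x, "abundance_table"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(x$sample_ids))
  names(paths) <- x$sample_ids
  for (s in x$sample_ids) {
    path <- file.path(outdir, paste0(s, suffix, ".tsv"))
    df <- data.frame(
      clade_name = paste0("k__Bacteria|s__", x$species_ids),
      relative_abundance = x$rel_abundance[s, ],
      estimated_number_of_reads_from_the_clade = x$read_counts[s, ],
      stringsAsFactors = FALSE
    )
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths[s] <- path
  }
  invisible(paths)
}

#' Centered log-ratio transform of estimated read counts
#'
#' Sequencing profiles are compositional: only ratios between taxa are
#' informative. The clr transform divides each sample's counts by their
#' geometric mean and takes logs, so transformed values are comparable
#' across samples. A pseudocount is added to the counts before the
#' geometric mean, which both avoids nonfinite values at zero counts and
#' makes every transformed row sum exactly to zero.
#'
#' @param x an [abundance_table()] (its `read_counts` are used) or a
#'   nonnegative numeric matrix, samples in rows.
#' @param pseudocount positive offset added to counts; default 1 read.
#'   `pseudocount = 0` is allowed for strictly positive counts.
#' @return numeric matrix of clr values with the same dimnames; rows sum
#'   to zero (within 1e-8).
#' @examples
#' clr_transform(matrix(c(0, 3, 15), 1, dimnames = list("s1", c("a","b","c"))))
#' @export
clr_transform <- function(x, pseudocount = 1) {
  counts <- if (inherits(x, "abundance_table")) x$read_counts else as.matrix(x)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (pseudocount == 0 && any(counts <= 0)) {
    stop("pseudocount 0 requires strictly positive counts")
  }
  lv <- log(counts + pseudocount)
  out <- lv - rowMeans(lv)
  attr(out, "pseudocount") <- pseudocount
  out
}
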