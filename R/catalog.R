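#' Load a mucin-degradation enzyme catalog
#'
#' The catalog lists the enzyme-commission (EC) numbers of mucosal glycan
#' degradation enzymes together with their enzyme class (glycoside
#' hydrolase, lyase, or sulfatase), CAZy GH family assignments, and two
#' flags: `versatility_excluded` marks the alpha-/beta-galactosidases
#' (3.2.1.22, 3.2.1.23), whose transcription alone does not qualify a
#' species as a mucin degrader because galactose is widely available from
#' dietary glycans; `active` marks ECs that are carried through the
#' analysis (the shipped default flags N-acetylglucosamine-6-sulfatase,
#' 3.1.6.14, inactive because it is detected in ~1% of samples and maps to
#' no reference genome).
#'
#' @param path path to a tab-separated catalog with columns `ec_id`,
#'   `name`, `enzyme_class`, `gh_families` (semicolon-separated, may be
#'   empty), `versatility_excluded`, `active`, or a YAML file with an
#'   `entries` list carrying the same fields. `NULL` (default) loads the
#'   catalog shipped with the package.
#' @return an `ec_catalog`: a data.frame with one row per EC and the
#'   columns above (plus any extra metadata columns present in the file).
#' @examples
#' cat <- load_ec_catalog()
#' subset(cat, active)$ec_id
#' @export
load_ec_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "mucin_ec_catalog.tsv",
                        package = "glycoguild", mustWork = TRUE)
  }
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    entries <- y$entries %||% y
    df <- do.call(rbind, lapply(entries, function(e) {
      data.frame(
        ec_id = e$ec_id, name = e$name,
        enzyme_class = e$enzyme_class,
        gh_families = paste(e$gh_families %||% character(), collapse = ";"),
        versatility_excluded = isTRUE(e$versatility_excluded),
        active = e$active %||% TRUE,
        stringsAsFactors = FALSE
      )
    }))
  } else {
    df <- read_tsv_artifact(path)
  }
  as_ec_catalog(df)
}

#' Construct and validate an EC catalog
#'
#' @param df data.frame with at least `ec_id`, `name`, `enzyme_class`;
#'   missing `gh_families`, `versatility_excluded` or `active` columns are
#'   filled with defaults (none, FALSE, TRUE).
#' @return validated `ec_catalog` data.frame.
#' @export
as_ec_catalog <- function(df) {
  required <- c("ec_id", "name", "enzyme_class")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("catalog is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (is.null(df$gh_families)) df$gh_families <- ""
  df$gh_families[is.na(df$gh_families)] <- ""
  if (is.null(df$versatility_excluded)) df$versatility_excluded <- FALSE
  if (is.null(df$active)) df$active <- TRUE
  df$versatility_excluded <- as.logical(df$versatility_excluded)
  df$active <- as.logical(df$active)
  bad <- !ec_id_ok(df$ec_id)
  if (any(bad)) {
    stop("malformed EC id(s): ", paste(df$ec_id[bad], collapse = ", "))
  }
  if (anyDuplicated(df$ec_id)) {
    stop("duplicate EC id(s) in catalog: ",
         paste(unique(df$ec_id[duplicated(df$ec_id)]), collapse = ", "))
  }
  known <- c("glycosyl_hydrolase", "lyase", "sulfatase")
  if (!all(df$enzyme_class %in% known)) {
    stop("enzyme_class must be one of: ", paste(known, collapse = ", "))
  }
  rownames(df) <- NULL
  class(df) <- c("ec_catalog", "data.frame")
  df
}

#' @export
print.ec_catalog <- function(x, ...) {
  cat(sprintf("EC catalog: %d entries (%d active, %d versatility-excluded)\n",
              nrow(x), sum(x$active), sum(x$versatility_excluded)))
  print.data.frame(x[, c("ec_id", "name", "enzyme_class", "active")], ...)
  invisible(x)
}

# ECs carried into the analysis.
active_ecs <- function(catalog) catalog$ec_id[catalog$active]

# ECs that do not count on their own towards versatility.
excluded_ecs <- function(catalog) catalog$ec_id[catalog$versatility_excluded]
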