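# Internal helpers shared across modules.

# Values at or below this magnitude are treated as exact zeros for all
# presence/absence logic (counts and cpm are reported at coarse precision by
# upstream profilers; tiny residues are numerical noise).
.ZERO_TOL <- 1e-12

is_zero <- function(x) abs(x) <= .ZERO_TOL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the random seed, evaluates `expr`, and restores the previous RNG
#' state so that callers' random streams are unaffected.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Write a data.frame as TSV with a provenance comment header.
write_tsv_artifact <- function(df, path, comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  header <- c(
    sprintf("# glycoguild %s",
            as.character(utils::packageVersion("glycoguild"))),
    if (!is.null(comment)) paste0("# ", comment)
  )
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_artifact <- function(path) {
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

# Stable short hash of an arbitrary R object (config fingerprinting).
object_hash <- function(x) {
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  writeLines(deparse(x, control = "all"), tmp)
  unname(tools::md5sum(tmp))
}

ec_id_ok <- function(ec) grepl("^[0-9]+\\.[0-9]+\\.[0-9]+\\.[0-9]+$", ec)

# Label used for the unattributed stratum of a functional table.
UNCLASSIFIED <- "UNCLASSIFIED"
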