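#' Per-species contribution to EC transcription
#'
#' Normalizes each species' transcript stratum to the total transcription
#' attributed to that EC in that sample, in percent. The denominator is
#' the community total (including the UNCLASSIFIED stratum), so per
#' (sample, EC) the species plus unclassified contributions close to
#' 100%. Samples where an EC's total is zero are excluded for that EC
#' (the contribution is undefined there).
#'
#' @param mt metatranscriptome [stratified_table()].
#' @param catalog optional EC catalog; restricts to its active ECs.
#' @param classified_only if `TRUE`, the denominator excludes the
#'   UNCLASSIFIED stratum.
#' @param tol consistency tolerance.
#' @return a `contribution_table` data.frame: `sample`, `ec`, `species`,
#'   `contribution` (%).
#' @export
contributions <- function(mt, catalog = NULL, classified_only = FALSE,
                          tol = 1e-6) {
  stopifnot(inherits(mt, "stratified_table"))
  ecs <- if (is.null(catalog)) mt$ec_ids else
    intersect(active_ecs(catalog), mt$ec_ids)
  s <- mt$strata[mt$strata$ec %in% ecs, , drop = FALSE]
  if (classified_only) {
    key <- paste(s$sample, s$ec, sep = "\t")
    cls <- s[s$species != UNCLASSIFIED, , drop = FALSE]
    totv <- tapply(cls$cpm, paste(cls$sample, cls$ec, sep = "\t"), sum)
    denom <- as.numeric(totv[key])
    denom[is.na(denom)] <- 0
  } else {
    tot <- community_totals(mt, ecs)
    denom <- tot[cbind(s$sample, s$ec)]
  }
  over <- s$cpm > denom + tol
  if (any(over)) {
    stop("stratum cpm exceeds the community total for ",
         sum(over), " record(s)")
  }
  keep <- denom > 0
  out <- data.frame(sample = s$sample[keep], ec = s$ec[keep],
                    species = s$species[keep],
                    contribution = 100 * s$cpm[keep] / denom[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("contribution_table", "data.frame")
  out
}

# samples x species matrix of contributions for one EC (NA where the EC
# total is zero, 0 where the EC is transcribed but the species silent).
contribution_matrix <- function(contrib, ec, samples, species) {
  d <- contrib[contrib$ec == ec, , drop = FALSE]
  m <- matrix(NA_real_, length(samples), length(species),
              dimnames = list(samples, species))
  on_samples <- unique(d$sample)
  m[on_samples, ] <- 0
  d <- d[d$species %in% species, , drop = FALSE]
  if (nrow(d)) m[cbind(d$sample, d$species)] <- d$contribution
  m
}

# Shared OLS summary: returns the pieces every fit reports. Aliased
# (perfectly collinear) predictors come back with NA estimate/p.
ols_fit <- function(y, X, response, predictors) {
  df <- data.frame(y = y, X, check.names = FALSE)
  fit <- stats::lm(y ~ ., data = df)
  sm <- summary(fit)
  co <- sm$coefficients
  rn <- gsub("`", "", rownames(co))
  est <- stats::setNames(rep(NA_real_, length(predictors)), predictors)
  pv <- est
  hit <- match(predictors, rn)
  est[!is.na(hit)] <- co[hit[!is.na(hit)], "Estimate"]
  pv[!is.na(hit)] <- co[hit[!is.na(hit)], "Pr(>|t|)"]
  f <- sm$fstatistic
  model_p <- if (is.null(f)) NA_real_ else
    unname(stats::pf(f[1], f[2], f[3], lower.tail = FALSE))
  list(response = response,
       predictors = predictors,
       coefficients = est,
       coef_p = pv,
       intercept = co[match("(Intercept)", rn), "Estimate"],
       model_p = model_p,
       adj_r2 = sm$adj.r.squared,
       n_obs = length(y))
}

#' Abundance-driven transcription of one species for one EC
#'
#' Ordinary least squares of the species' contribution to the EC's
#' transcription (%) on its own clr-transformed abundance, over the
#' samples in which the EC is transcribed at all. The adjusted R-squared
#' measures how much of the transcriptional variation the species' own
#' abundance explains ("abundance-driven transcription"); it can be
#' slightly negative for uninformative fits.
#'
#' @param contrib a [contributions()] table.
#' @param clr clr abundance matrix, samples x species.
#' @param ec,species the (EC, species) pair to fit.
#' @param alpha model significance level (default 0.05).
#' @param min_n minimum number of observations (default 10).
#' @return an `lm_fit` list: response, predictors, coefficients, coef_p,
#'   model_p, adj_r2, n_obs, significant; or a `skipped_fit` (with a
#'   `reason`) when the fit is undefined.
#' @export
abundance_driven_fit <- function(contrib, clr, ec, species,
                                 alpha = 0.05, min_n = 10) {
  d <- contrib[contrib$ec == ec, , drop = FALSE]
  samples <- intersect(unique(d$sample), rownames(clr))
  if (length(samples) < min_n) return(skipped_fit("too few samples"))
  y <- stats::setNames(rep(0, length(samples)), samples)
  dsp <- d[d$species == species & d$sample %in% samples, , drop = FALSE]
  y[dsp$sample] <- dsp$contribution
  x <- clr[samples, species]
  if (stats::var(x) == 0) return(skipped_fit("constant predictor"))
  if (stats::var(y) == 0) return(skipped_fit("constant response"))
  out <- ols_fit(unname(y), stats::setNames(data.frame(x), species),
                 response = paste0(species, " [% of ", ec, "]"),
                 predictors = species)
  out$ec <- ec
  out$species <- species
  out$significant <- !is.na(out$model_p) && out$model_p < alpha
  class(out) <- "lm_fit"
  out
}

skipped_fit <- function(reason) {
  structure(list(skipped = TRUE, reason = reason), class = "skipped_fit")
}

#' @export
print.lm_fit <- function(x, ...) {
  cat(sprintf("lm_fit: %s ~ %s\n", x$response,
              paste(x$predictors, collapse = " + ")))
  cat(sprintf("  n = %d, adj R^2 = %.4f, model p = %.3g%s\n", x$n_obs,
              x$adj_r2, x$model_p,
              if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

#' Abundance-driven fits for all prevalent (EC, species) pairs
#'
#' @param contrib a [contributions()] table.
#' @param clr clr abundance matrix.
#' @param pairs data.frame with columns `ec`, `species` (e.g. the
#'   prevalent pairs from [prevalent_pairs()]).
#' @param alpha,min_n see [abundance_driven_fit()].
#' @return data.frame with one row per attempted fit: `ec`, `species`,
#'   `slope`, `coef_p`, `model_p`, `adj_r2`, `n_obs`, `significant`,
#'   `skipped`, `reason`.
#' @export
abundance_driven_fits <- function(contrib, clr, pairs, alpha = 0.05,
                                  min_n = 10) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    f <- abundance_driven_fit(contrib, clr, pairs$ec[i], pairs$species[i],
                              alpha = alpha, min_n = min_n)
    if (inherits(f, "skipped_fit")) {
      data.frame(ec = pairs$ec[i], species = pairs$species[i],
                 slope = NA_real_, coef_p = NA_real_, model_p = NA_real_,
                 adj_r2 = NA_real_, n_obs = NA_integer_,
                 significant = NA, skipped = TRUE,
                 reason = f$reason, stringsAsFactors = FALSE)
    } else {
      data.frame(ec = f$ec, species = f$species,
                 slope = unname(f$coefficients[1]),
                 coef_p = unname(f$coef_p[1]), model_p = f$model_p,
                 adj_r2 = f$adj_r2, n_obs = f$n_obs,
                 significant = f$significant, skipped = FALSE,
                 reason = "", stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Prevalently transcribing (EC, species) pairs
#'
#' The species eligible for the per-EC linear models: detectable
#' transcription in at least `min_prevalence` of the samples in which
#' the EC is transcribed, optionally restricted to a degrader set.
#'
#' @param mt metatranscriptome [stratified_table()].
#' @param catalog EC catalog (active ECs are considered).
#' @param species optional restriction (e.g. `prevalent_versatile`).
#' @param min_prevalence threshold, `>=` semantics (default 0.10).
#' @return data.frame `ec`, `species`, `prevalence`.
#' @export
prevalent_pairs <- function(mt, catalog, species = NULL,
                            min_prevalence = 0.10) {
  prev <- transcription_prevalence(mt, intersect(active_ecs(catalog),
                                                 mt$ec_ids))
  keep <- !is.na(prev$prevalence) & prev$prevalence >= min_prevalence
  if (!is.null(species)) keep <- keep & prev$species %in% species
  out <- prev[keep, c("ec", "species", "prevalence")]
  rownames(out) <- NULL
  out
}

#' Response-predictor models for one EC
#'
#' For each prevalently transcribing species of the EC (the response),
#' fits an ordinary least squares model of its contribution to the EC's
#' transcription (%) on the clr abundances of all *other* prevalent
#' transcribers of the same EC. Every non-intercept coefficient with
#' p < `alpha` becomes a directed edge predictor -> response carrying
#' the coefficient's sign: a negative coefficient means the response
#' species' transcription is low where the predictor is abundant
#' (inhibition), a positive one means facilitation.
#'
#' @param contrib a [contributions()] table.
#' @param clr clr abundance matrix.
#' @param ec the EC to model.
#' @param transcribers prevalent transcriber species of this EC (at
#'   least 2).
#' @param alpha coefficient significance level (default 0.05).
#' @param min_n minimum observations (default 10; models with
#'   `n_obs <= p + 1` are skipped).
#' @param p_adjust multiplicity correction applied per model to the
#'   coefficient p-values (`"none"`, default, or any [stats::p.adjust()]
#'   method).
#' @return list with `edges` (data.frame ec, predictor, response,
#'   coefficient, p, sign), `fits` (per-response summaries incl. adj_r2)
#'   and `skipped` (responses not modelled, with reasons).
#' @export
response_predictor_fit <- function(contrib, clr, ec, transcribers,
                                   alpha = 0.05, min_n = 10,
                                   p_adjust = "none") {
  if (length(transcribers) < 2) {
    stop("need at least 2 prevalent transcribers for EC ", ec)
  }
  d <- contrib[contrib$ec == ec, , drop = FALSE]
  samples <- intersect(unique(d$sample), rownames(clr))
  edges <- list()
  fits <- list()
  skipped <- list()
  for (resp in transcribers) {
    preds <- setdiff(transcribers, resp)
    if (length(samples) < max(min_n, length(preds) + 2)) {
      skipped[[resp]] <- data.frame(ec = ec, response = resp,
                                    reason = "too few samples",
                                    stringsAsFactors = FALSE)
      next
    }
    y <- stats::setNames(rep(0, length(samples)), samples)
    dr <- d[d$species == resp & d$sample %in% samples, , drop = FALSE]
    y[dr$sample] <- dr$contribution
    if (stats::var(y) == 0) {
      skipped[[resp]] <- data.frame(ec = ec, response = resp,
                                    reason = "constant response",
                                    stringsAsFactors = FALSE)
      next
    }
    X <- clr[samples, preds, drop = FALSE]
    keep_pred <- apply(X, 2, stats::var) > 0
    if (!all(keep_pred)) {
      preds <- preds[keep_pred]
      X <- X[, keep_pred, drop = FALSE]
    }
    if (length(preds) == 0) {
      skipped[[resp]] <- data.frame(ec = ec, response = resp,
                                    reason = "no varying predictors",
                                    stringsAsFactors = FALSE)
      next
    }
    f <- ols_fit(unname(y), as.data.frame(X), response = resp,
                 predictors = preds)
    p_use <- stats::p.adjust(f$coef_p, method = p_adjust)
    fits[[resp]] <- data.frame(
      ec = ec, response = resp, adj_r2 = f$adj_r2, model_p = f$model_p,
      n_obs = f$n_obs, n_predictors = length(preds),
      condition_number = kappa(cbind(1, X), exact = TRUE),
      stringsAsFactors = FALSE)
    sig <- which(p_use < alpha)
    if (length(sig)) {
      edges[[resp]] <- data.frame(
        ec = ec, predictor = preds[sig], response = resp,
        coefficient = unname(f$coefficients[sig]),
        p = unname(f$coef_p[sig]),
        sign = ifelse(f$coefficients[sig] > 0, "positive", "negative"),
        stringsAsFactors = FALSE)
    }
  }
  empty_edges <- data.frame(ec = character(), predictor = character(),
                            response = character(),
                            coefficient = numeric(), p = numeric(),
                            sign = character(), stringsAsFactors = FALSE)
  list(edges = if (length(edges)) do.call(rbind, c(edges, list(
         make.row.names = FALSE))) else empty_edges,
       fits = if (length(fits)) do.call(rbind, c(fits, list(
         make.row.names = FALSE))) else NULL,
       skipped = if (length(skipped)) do.call(rbind, c(skipped, list(
         make.row.names = FALSE))) else NULL)
}

#' Consensus network across per-EC response-predictor networks
#'
#' Groups directed (predictor, response) pairs across the per-EC edge
#' sets, counts positive and negative occurrences, and labels each pair
#' `always_positive`, `always_negative`, or `mixed` (the label is
#' `mixed` exactly when both signs occur).
#'
#' @param edgesets either one combined edge data.frame (as returned in
#'   `edges` by [response_predictor_fit()]) or a list of them.
#' @return data.frame `predictor`, `response`, `n_positive`,
#'   `n_negative`, `n_total`, `label`, `ecs` (semicolon-joined).
#' @export
consensus_edges <- function(edgesets) {
  if (is.data.frame(edgesets)) edgesets <- list(edgesets)
  all_edges <- do.call(rbind, edgesets)
  if (is.null(all_edges) || nrow(all_edges) == 0) {
    return(data.frame(predictor = character(), response = character(),
                      n_positive = integer(), n_negative = integer(),
                      n_total = integer(), label = character(),
                      ecs = character(), stringsAsFactors = FALSE))
  }
  key <- paste(all_edges$predictor, all_edges$response, sep = "\t")
  rows <- lapply(split(all_edges, key), function(d) {
    npos <- sum(d$sign == "positive")
    nneg <- sum(d$sign == "negative")
    data.frame(predictor = d$predictor[1], response = d$response[1],
               n_positive = npos, n_negative = nneg,
               n_total = npos + nneg,
               label = if (npos > 0 && nneg > 0) "mixed" else
                 if (npos > 0) "always_positive" else "always_negative",
               ecs = paste(sort(d$ec), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$predictor, out$response), , drop = FALSE]
}

#' Competitive-opportunistic continuum summary
#'
#' Summarizes, per species, (i) the median adjusted R-squared of its
#' abundance-driven fits across ECs (the "percentage of abundance-driven
#' transcription"), (ii) the average number of species it inhibits
#' (significant negative response-predictor coefficients with the
#' species as predictor, averaged over the EC networks in which it was
#' an eligible predictor) and (iii) the analogous average number
#' facilitated. Species with median adjusted R-squared above `threshold`
#' are classed competitive, the rest opportunistic. Two cross-species
#' trends are fitted: average inhibited on median R-squared, and average
#' facilitated on average inhibited.
#'
#' @param fits data.frame from [abundance_driven_fits()].
#' @param edges combined response-predictor edge data.frame.
#' @param eligible data.frame `ec`, `species` of eligible transcribers
#'   per EC network (e.g. [prevalent_pairs()]); defines each species'
#'   predictor-eligibility denominator.
#' @param threshold competitive classification threshold on the median
#'   adjusted R-squared (default 0.2).
#' @return an `ecology_summary`: list with `species` (data.frame:
#'   median_adj_r2, avg_inhibited, avg_facilitated, n_ec_networks,
#'   class) and `trends` (list of the two fitted trends with slope,
#'   model_p, adj_r2).
#' @export
ecology_summary <- function(fits, edges, eligible, threshold = 0.2) {
  ok <- fits[!fits$skipped & !is.na(fits$adj_r2), , drop = FALSE]
  med <- tapply(ok$adj_r2, ok$species, stats::median)
  # EC networks in which each species is an eligible predictor: the
  # networks it belongs to (it predicts every other response there).
  n_networks <- tapply(eligible$ec, eligible$species,
                       function(e) length(unique(e)))
  species <- sort(intersect(names(med), names(n_networks)))
  if (length(species) == 0) stop("no species with abundance-driven fits")
  dropped <- setdiff(names(med), species)
  if (length(dropped)) {
    message("excluded from the continuum (in no EC network): ",
            paste(dropped, collapse = ", "))
  }
  count_edges <- function(sgn) {
    e <- edges[edges$sign == sgn, , drop = FALSE]
    tapply(e$response, paste(e$predictor), length)
  }
  npos <- count_edges("positive")
  nneg <- count_edges("negative")
  df <- data.frame(
    species = species,
    median_adj_r2 = as.numeric(med[species]),
    n_ec_networks = as.integer(n_networks[species]),
    avg_inhibited = as.numeric(ifelse(is.na(nneg[species]), 0,
                                      nneg[species])) /
      as.integer(n_networks[species]),
    avg_facilitated = as.numeric(ifelse(is.na(npos[species]), 0,
                                        npos[species])) /
      as.integer(n_networks[species]),
    stringsAsFactors = FALSE)
  df$class <- ifelse(df$median_adj_r2 > threshold, "competitive",
                     "opportunistic")
  trend <- function(y, x) {
    if (length(unique(x)) < 3) {
      return(list(slope = NA_real_, model_p = NA_real_,
                  adj_r2 = NA_real_))
    }
    f <- ols_fit(y, data.frame(x = x), "trend", "x")
    list(slope = unname(f$coefficients[1]), model_p = f$model_p,
         adj_r2 = f$adj_r2)
  }
  structure(
    list(species = df,
         trends = list(
           inhibited_vs_r2 = trend(df$avg_inhibited, df$median_adj_r2),
           facilitated_vs_inhibited = trend(df$avg_facilitated,
                                            df$avg_inhibited)),
         threshold = threshold),
    class = "ecology_summary")
}

#' @export
print.ecology_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "ecology_summary: %d species (%d competitive, %d opportunistic ",
    "at median adj R^2 > %.2f)\n"),
    nrow(x$species), sum(x$species$class == "competitive"),
    sum(x$species$class == "opportunistic"), x$threshold))
  t1 <- x$trends$inhibited_vs_r2
  t2 <- x$trends$facilitated_vs_inhibited
  cat(sprintf("  avg inhibited ~ median R^2:   slope %.3f, p %.3g, adj R^2 %.3f\n",
              t1$slope, t1$model_p, t1$adj_r2))
  cat(sprintf("  avg facilitated ~ inhibited:  slope %.3f, p %.3g, adj R^2 %.3f\n",
              t2$slope, t2$model_p, t2$adj_r2))
  invisible(x)
}

#' Fit all response-predictor networks of a study
#'
#' Runs [response_predictor_fit()] for every EC with at least two
#' prevalent transcribers and combines the edge sets.
#'
#' @param contrib a [contributions()] table.
#' @param clr clr abundance matrix.
#' @param pairs eligible (EC, species) pairs from [prevalent_pairs()].
#' @param alpha,min_n,p_adjust see [response_predictor_fit()].
#' @return list with `edges` (combined), `fits`, `skipped`, `consensus`
#'   (from [consensus_edges()]) and `eligible` (the pairs used).
#' @export
response_predictor_networks <- function(contrib, clr, pairs,
                                        alpha = 0.05, min_n = 10,
                                        p_adjust = "none") {
  ecs <- unique(pairs$ec)
  res <- list()
  for (ec in ecs) {
    tr <- pairs$species[pairs$ec == ec]
    if (length(tr) < 2) next
    res[[ec]] <- response_predictor_fit(contrib, clr, ec, tr,
                                        alpha = alpha, min_n = min_n,
                                        p_adjust = p_adjust)
  }
  edges <- do.call(rbind, c(lapply(res, `[[`, "edges"),
                            list(make.row.names = FALSE)))
  fits <- do.call(rbind, c(lapply(res, `[[`, "fits"),
                           list(make.row.names = FALSE)))
  skipped <- do.call(rbind, c(lapply(res, `[[`, "skipped"),
                              list(make.row.names = FALSE)))
  used <- pairs[pairs$ec %in% names(res), , drop = FALSE]
  list(edges = edges, fits = fits, skipped = skipped,
       consensus = consensus_edges(edges), eligible = used)
}
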