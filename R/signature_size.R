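# Signature-size resampling, cross-cohort gene consistency, refined
# signatures, and the nested full-vs-refined evaluation.

.default_sizes <- function() c(1, 2, seq(4, 30, by = 2), 31)

# distinct size-s subsets of 1..g: exhaustive when the subset space is small,
# otherwise sampled without replacement (deduplicated) up to maxReps
.draw_subsets <- function(g, s, maxReps) {
  total <- choose(g, s)
  if (total <= maxReps) {
    return(combn(g, s, simplify = FALSE))
  }
  seen <- new.env(hash = TRUE)
  out <- vector("list", maxReps)
  got <- 0L
  while (got < maxReps) {
    draw <- sort(sample.int(g, s))
    key <- paste(draw, collapse = ",")
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      got <- got + 1L
      out[[got]] <- draw
    }
  }
  out
}

# per-subset two-sided p-value of the mean-score predictor in one cohort
.subset_pvalues <- function(Z, subsets, clin_df, kind) {
  if (kind == "time_to_event") {
    y <- Surv(clin_df$time, clin_df$event)
    vapply(subsets, function(idx) {
      sc <- colMeans(Z[idx, , drop = FALSE])
      f <- .fast_cox(sc, y)
      if (is.null(f)) NA_real_ else f$p_score
    }, 0)
  } else {
    lab <- clin_df$label
    vapply(subsets, function(idx) {
      sc <- colMeans(Z[idx, , drop = FALSE])
      tryCatch(suppressWarnings(
        wilcox.test(sc[lab == 1], sc[lab == 0])$p.value),
        error = function(e) NA_real_)
    }, 0)
  }
}

#' Random-signature size curves
#'
#' For each cohort and signature size s, draws up to \code{maxReps} distinct
#' size-s subsets of the proliferation genes available on that cohort's
#' platform (all subsets when fewer exist), scores each subset as the mean
#' of its z-normalized rows, tests each score against the cohort's endpoint,
#' and records the proportion of subsets significant at p < 0.05. Sizes
#' exceeding a cohort's available gene count are skipped for that cohort
#' (with a warning) and the full available count is always evaluated (it is
#' the single full-signature test).
#'
#' @param ccpGenes character vector, the full signature's gene symbols.
#' @param cohorts list of z-normalized \linkS4class{PrognosticCohort}s.
#' @param sizes signature sizes to evaluate (default 1, 2, 4, 6, ..., 30, 31).
#' @param maxReps maximum subsets per (cohort, size) (default 10000).
#' @param seed integer seed; results are deterministic given the seed (the
#'   RNG state is restored on exit). Each cohort uses seed + its index.
#' @param sigAlpha significance threshold (default 0.05).
#' @return data.frame (cohort, size, n_reps, prop_significant) with the full
#'   per-size p-value lists in \code{attr(, "pvalues")} (nested list:
#'   cohort -> size).
#' @export
randomSignatureCurves <- function(ccpGenes, cohorts, sizes = .default_sizes(),
                                  maxReps = 10000, seed = 1,
                                  sigAlpha = 0.05) {
  stopifnot(length(ccpGenes) > 0, length(cohorts) > 0)
  rows <- list(); pvals <- list()
  for (i in seq_along(cohorts)) {
    co <- cohorts[[i]]
    if (!isNormalized(co)) stop("cohorts must be z-normalized")
    avail <- intersect(ccpGenes, rownames(co))
    g <- length(avail)
    if (g == 0) {
      warning("cohort ", cohortId(co), ": no signature genes on platform; skipped")
      next
    }
    skipped <- sizes[sizes > g]
    if (length(skipped))
      warning("cohort ", cohortId(co), ": size(s) ",
              paste(skipped, collapse = ", "), " exceed the ", g,
              " available genes; skipped")
    sz <- sort(unique(c(sizes[sizes <= g], g)))
    Z <- assay(co, "exprs")[avail, , drop = FALSE]
    cd <- clinicalTable(co)
    kind <- endpointKind(co)
    cd <- if (kind == "time_to_event")
      cd[!is.na(cd$time) & !is.na(cd$event), , drop = FALSE]
    else cd[!is.na(cd$label), , drop = FALSE]
    Z <- Z[, cd$sample_id, drop = FALSE]
    co_p <- with_seed(as.integer(seed + i), {
      lapply(sz, function(s) {
        subsets <- .draw_subsets(g, s, maxReps)
        .subset_pvalues(Z, subsets, cd, kind)
      })
    })
    names(co_p) <- as.character(sz)
    pvals[[cohortId(co)]] <- co_p
    rows[[length(rows) + 1]] <- data.frame(
      cohort = cohortId(co), size = sz,
      n_reps = vapply(co_p, length, 0L),
      prop_significant = vapply(co_p, function(p)
        mean(p < sigAlpha, na.rm = TRUE), 0))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "pvalues") <- pvals
  out
}

#' Plateau size of a proportion-significant curve
#'
#' The smallest signature size whose proportion of significant random
#' signatures reaches \code{frac} (default 95\%) of the full-size
#' proportion. When the full signature itself is not significant (full-size
#' proportion 0) the threshold is vacuous and \code{NA} (not applicable) is
#' returned.
#'
#' @param curve data.frame with \code{size} and \code{prop_significant}
#'   columns for a single cohort (one row per size).
#' @param frac fraction of the full-size proportion (default 0.95).
#' @return The plateau size, or \code{NA_integer_}.
#' @export
plateauSize <- function(curve, frac = 0.95) {
  stopifnot(nrow(curve) >= 1)
  curve <- curve[order(curve$size), , drop = FALSE]
  full <- curve$prop_significant[nrow(curve)]
  if (full == 0) return(NA_integer_)
  hit <- which(curve$prop_significant >= frac * full)
  as.integer(curve$size[hit[1]])
}

#' Rank genes by cross-cohort prognostic consistency
#'
#' For each gene, counts the cohorts in which its univariate test is
#' significant (p < \code{alpha}); genes are ranked by that count
#' (descending), then mean p across tested cohorts (ascending), then symbol.
#'
#' @param cohorts list of z-normalized \linkS4class{PrognosticCohort}s.
#' @param genes gene symbols to rank.
#' @param alpha per-cohort significance threshold (default 0.05).
#' @return data.frame (gene, n_cohorts_tested, n_cohorts_significant,
#'   mean_p), ranked.
#' @export
rankGenesByConsistency <- function(cohorts, genes, alpha = 0.05) {
  stopifnot(length(genes) > 0)
  per_gene <- lapply(genes, function(g) {
    ps <- numeric(0)
    for (co in cohorts) {
      if (!g %in% rownames(co)) next
      s <- setNames(assay(co, "exprs")[g, ], colnames(co))
      p <- tryCatch(.test_continuous_core(s, co)@p, error = function(e) NA_real_)
      if (!is.na(p)) ps <- c(ps, p)
    }
    data.frame(gene = g, n_cohorts_tested = length(ps),
               n_cohorts_significant = sum(ps < alpha),
               mean_p = if (length(ps)) mean(ps) else NA_real_)
  })
  tab <- do.call(rbind, per_gene)
  if (all(tab$n_cohorts_tested == 0)) stop("no gene measured in any cohort")
  tab <- tab[order(-tab$n_cohorts_significant, tab$mean_p, tab$gene), ,
             drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Build a refined signature from a consistency ranking
#'
#' Takes the top k genes of a \code{\link{rankGenesByConsistency}} table;
#' refined signatures of increasing k are nested by construction.
#'
#' @param consistency ranked consistency table.
#' @param k number of genes (1 <= k <= nrow(consistency)).
#' @param name signature name (default "CCP-k").
#' @return A \linkS4class{GeneSignature}.
#' @export
refineSignature <- function(consistency, k, name = NULL) {
  if (!(length(k) == 1 && k >= 1 && k == round(k)))
    stop("'k' must be a positive integer")
  if (k > nrow(consistency)) stop("'k' exceeds the number of ranked genes")
  if (is.null(name)) name <- sprintf("CCP-%d", k)
  geneSignature(name, consistency$gene[seq_len(k)])
}

#' Does the full signature add value over a refined signature plus a
#' clinical risk score?
#'
#' Nested likelihood-ratio test of the full-signature score against the base
#' model (refined-signature score + clinical risk covariate): the external
#' validation logic for refined signatures.
#'
#' @param clin a \linkS4class{PrognosticCohort} or clinical data.frame with
#'   a time-to-event endpoint.
#' @param fullScore,refinedScore \linkS4class{SignatureScore}s or numeric
#'   vectors aligned with the clinical samples.
#' @param riskCovariate numeric clinical risk score (e.g. a surgical risk
#'   index), aligned with the clinical samples.
#' @return A \linkS4class{PrognosticResult} (\code{method = "lrt"}).
#' @export
fullVsRefinedTest <- function(clin, fullScore, refinedScore, riskCovariate) {
  fs <- if (is(fullScore, "SignatureScore")) scoreValues(fullScore) else fullScore
  rs <- if (is(refinedScore, "SignatureScore")) scoreValues(refinedScore) else refinedScore
  base <- data.frame(refined = unname(rs), risk = unname(riskCovariate))
  addedValueTest(clin, base, unname(fs))
}
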