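# Over-representation of prognostic gene lists in a module catalog, with the
# cross-cohort ranking and per-cohort "top hit" rules.

#' Hypergeometric over-representation of modules in a gene list
#'
#' For each module (gene set) in the catalog, tests whether the gene list
#' contains more module genes than expected when drawing \code{n} genes from
#' the \code{N}-gene universe, by the one-sided hypergeometric tail
#' P(X >= k). P-values are Benjamini-Hochberg adjusted across the modules of
#' the table. Catalog genes outside the universe are clipped (with a
#' message); module sizes \code{K} refer to the clipped sets.
#'
#' @param geneList character vector, the prognostic genes (must lie in the
#'   universe).
#' @param universe character vector, all genes tested (the measured genes of
#'   the cohort after collapsing).
#' @param catalog named list of gene sets (see \code{\link{readGMT}}).
#' @param cohortId identifier stored with the table.
#' @param ease if TRUE, applies the conservative one-removed variant (the
#'   tail is evaluated at k - 1 overlap genes); default FALSE, the plain
#'   hypergeometric tail.
#' @return data.frame (module_id, k_overlap, K_module, n_list, N_universe,
#'   p, fdr) with attribute \code{cohort_id}.
#' @export
overrepresentation <- function(geneList, universe, catalog, cohortId = "cohort",
                               ease = FALSE) {
  universe <- unique(universe)
  geneList <- unique(geneList)
  if (!all(geneList %in% universe)) stop("gene list contains genes outside the universe")
  clipped <- lapply(catalog, function(g) intersect(unique(g), universe))
  n_out <- sum(lengths(catalog) - lengths(clipped))
  if (n_out > 0) message(n_out, " catalog gene(s) outside the universe clipped")
  if (length(geneList) == 0) warning("empty gene list: all p-values are 1")
  N <- length(universe); n <- length(geneList)
  rows <- lapply(names(clipped), function(id) {
    K <- length(clipped[[id]])
    k <- length(intersect(clipped[[id]], geneList))
    keff <- if (ease) max(k - 1, 0) else k
    p <- if (keff == 0) 1 else phyper(keff - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(module_id = id, k_overlap = k, K_module = K,
               n_list = n, N_universe = N, p = p)
  })
  tab <- do.call(rbind, rows)
  tab$fdr <- p.adjust(tab$p, method = "BH")
  attr(tab, "cohort_id") <- cohortId
  tab
}

#' Rank modules by cross-cohort consistency
#'
#' Modules are ranked first by the number of cohorts in which they are
#' significant (FDR below \code{fdrCut}), descending, then by their mean
#' p-value across the cohorts where they were tested, ascending; remaining
#' ties break by module id.
#'
#' @param tables list of enrichment tables from
#'   \code{\link{overrepresentation}} (one per cohort).
#' @param fdrCut FDR significance cut (default 0.20).
#' @return data.frame (module_id, n_cohorts_significant, n_cohorts_tested,
#'   mean_p), ranked.
#' @export
rankModules <- function(tables, fdrCut = 0.20) {
  if (length(tables) == 0) stop("need at least one enrichment table")
  all_tab <- do.call(rbind, lapply(tables, function(t)
    data.frame(module_id = t$module_id, p = t$p, fdr = t$fdr)))
  agg <- split(all_tab, all_tab$module_id)
  out <- do.call(rbind, lapply(agg, function(d)
    data.frame(module_id = d$module_id[1],
               n_cohorts_significant = sum(d$fdr < fdrCut),
               n_cohorts_tested = nrow(d),
               mean_p = mean(d$p))))
  out <- out[order(-out$n_cohorts_significant, out$mean_p, out$module_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' The "top hit" module of one cohort
#'
#' Among the modules that are significant (FDR below \code{fdrCut}) in at
#' least two cohorts overall, returns the one with the lowest FDR in the
#' given cohort; \code{NA} when no module qualifies.
#'
#' @param tables list of enrichment tables (one per cohort), each carrying a
#'   \code{cohort_id} attribute.
#' @param cohortId the cohort whose top hit is wanted.
#' @param fdrCut FDR significance cut (default 0.20).
#' @return Module id, or \code{NA_character_}.
#' @export
topHit <- function(tables, cohortId, fdrCut = 0.20) {
  ids <- vapply(tables, function(t) attr(t, "cohort_id"), "")
  if (!cohortId %in% ids) stop("unknown cohort id: ", cohortId)
  sig_counts <- table(unlist(lapply(tables, function(t)
    t$module_id[t$fdr < fdrCut])))
  multi <- names(sig_counts)[sig_counts >= 2]
  if (length(multi) == 0) return(NA_character_)
  tab <- tables[[which(ids == cohortId)[1]]]
  tab <- tab[tab$module_id %in% multi, , drop = FALSE]
  if (nrow(tab) == 0) return(NA_character_)
  tab <- tab[order(tab$fdr, tab$p, tab$module_id), , drop = FALSE]
  tab$module_id[1]
}
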