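#' Hypergeometric upper-tail over-representation p-value
#'
#' Probability of observing at least \code{k} pathway members in a selected
#' feature panel when \code{K} features are drawn without replacement from a
#' measured background of \code{m} features of which \code{N} belong to the
#' pathway (its effective size): P(X >= k), inclusive of the observed count.
#' Degenerate urns return 1: a pathway with no measured members (N = 0), an
#' empty panel (K = 0), or an observed count of 0 carry no evidence.
#'
#' @param k observed pathway members in the panel.
#' @param K panel size (selected features).
#' @param N effective pathway size in the namespace.
#' @param m background size (measured features).
#' @return p-value in (0, 1].
#' @export
hypergeom_tail <- function(k, K, N, m) {
  .check(all(N >= 0) && all(N <= m), "effective size N outside [0, m]")
  .check(all(K >= 0) && all(K <= m), "panel size K outside [0, m]")
  .check(all(k >= 0) && all(k <= pmin(K, N)),
         "observed count k outside [0, min(K, N)]")
  p <- ifelse(k == 0, 1,
              stats::phyper(k - 1, m = N, n = m - N, k = K,
                            lower.tail = FALSE))
  pmin(1, pmax(p, .Machine$double.xmin))
}

#' Per-pathway over-representation for one feature panel
#'
#' Counts each pathway's measured members inside the panel and scores
#' over-representation with [hypergeom_tail()] against the namespace
#' background. Pathways with no measured member in the panel's namespace
#' get p = 1.
#'
#' @param panel a `feature_panel` ([select_significant()]).
#' @param db a `pathway_db`.
#' @return data.frame with columns \code{pathway_id}, \code{N}, \code{k},
#'   \code{p} (one row per pathway, in database order).
#' @export
enrich <- function(panel, db) {
  ns <- panel$namespace
  .check(ns %in% c("gene", "metabolite"), "panel namespace missing")
  background <- if (ns == "gene") db$measured_genes else db$measured_metabolites
  m <- length(background)
  stray <- setdiff(panel$selected, background)
  .check(length(stray) == 0,
         "panel features absent from the %s background (universe mismatch): %s",
         ns, paste(utils::head(stray, 3), collapse = ", "))
  K <- length(panel$selected)
  member_field <- if (ns == "gene") "probe_measured" else "met_measured"
  N <- vapply(db$pathways, function(pw) length(pw[[member_field]]), 0L)
  k <- vapply(db$pathways, function(pw)
    sum(panel$selected %in% pw[[member_field]]), 0L)
  data.frame(pathway_id = names(db$pathways),
             N = N, k = k,
             p = hypergeom_tail(k, K, N, m),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Combine gene and metabolite pathway p-values into a joint probability
#'
#' The inter-omic joint probability of association is the plain product
#' p_J = p_G * p_M, justified by independence of the two measurement
#' platforms. A namespace with nothing measured for a pathway contributes
#' p = 1, so single-omic evidence passes through unchanged. The product is
#' the reported default; \code{method = "fisher"} gives the calibrated
#' chi-squared combination of the same two p-values for comparison (the
#' product of two uniforms is not itself uniform).
#'
#' @param p_G gene-side p-value(s) in (0, 1].
#' @param p_M metabolite-side p-value(s) in (0, 1].
#' @param method \code{"product"} (default) or \code{"fisher"}.
#' @return joint p-value vector.
#' @export
combine_joint <- function(p_G, p_M, method = c("product", "fisher")) {
  method <- match.arg(method)
  .check(all(p_G > 0 & p_G <= 1), "p_G outside (0, 1]")
  .check(all(p_M > 0 & p_M <= 1), "p_M outside (0, 1]")
  if (method == "product") {
    p_G * p_M
  } else {
    stats::pchisq(-2 * (log(p_G) + log(p_M)), df = 4, lower.tail = FALSE)
  }
}

#' Joint inter-omic enrichment for one drug
#'
#' Runs [enrich()] for the gene and metabolite panels of one drug and
#' combines the per-pathway p-values with [combine_joint()].
#'
#' @param gene_panel gene-namespace `feature_panel`.
#' @param met_panel metabolite-namespace `feature_panel`.
#' @param db a `pathway_db`.
#' @param alpha pathway significance level (default 0.05, strict "<").
#' @return an `enrichment_result` data.frame with columns \code{pathway_id},
#'   \code{source}, \code{N_G}, \code{k_G}, \code{p_G}, \code{N_M},
#'   \code{k_M}, \code{p_M}, \code{p_J}, \code{sig_gene}, \code{sig_met},
#'   \code{sig_joint}.
#' @export
enrich_joint <- function(gene_panel, met_panel, db, alpha = 0.05) {
  eg <- enrich(gene_panel, db)
  em <- enrich(met_panel, db)
  res <- data.frame(
    pathway_id = eg$pathway_id,
    source = vapply(db$pathways, function(pw)
      if (is.null(pw$source) || is.na(pw$source)) NA_character_ else pw$source,
      NA_character_),
    N_G = eg$N, k_G = eg$k, p_G = eg$p,
    N_M = em$N, k_M = em$k, p_M = em$p,
    p_J = combine_joint(eg$p, em$p),
    row.names = NULL, stringsAsFactors = FALSE
  )
  res$sig_gene <- res$p_G < alpha
  res$sig_met <- res$p_M < alpha
  res$sig_joint <- res$p_J < alpha
  structure(res, alpha = alpha, drug_id = gene_panel$drug_id,
            class = c("enrichment_result", "data.frame"))
}

#' Significant pathways at a threshold
#'
#' Returns the pathways whose p-value of the chosen mode is strictly below
#' \code{alpha}; a pathway with p exactly equal to alpha is not significant.
#'
#' @param results an `enrichment_result` ([enrich_joint()]).
#' @param alpha significance level in (0, 1); default 0.05.
#' @param mode which evidence to threshold: \code{"joint"} (p_J),
#'   \code{"gene"} (p_G) or \code{"metabolite"} (p_M).
#' @return character vector of pathway IDs.
#' @export
significant_pathways <- function(results, alpha = 0.05,
                                 mode = c("joint", "gene", "metabolite")) {
  mode <- match.arg(mode)
  .check(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  col <- switch(mode, joint = "p_J", gene = "p_G", metabolite = "p_M")
  results$pathway_id[results[[col]] < alpha]
}
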