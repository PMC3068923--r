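#' Default currency metabolites
#'
#' Ubiquitous compounds that appear in many pathways without conferring
#' specificity; they are stripped from every pathway and from the metabolite
#' background before enrichment. Default: phosphate, diphosphate and NADP+.
#'
#' @return character vector of compound names.
#' @export
default_currency_metabolites <- function() {
  c("phosphate", "diphosphate", "NADP+")
}

#' Build a two-namespace pathway database
#'
#' Joins gene-side and metabolite-side membership sets on pathway ID,
#' expands protein members to measured probesets through the ID map, removes
#' currency metabolites, and computes each pathway's effective size per
#' namespace: the number of its members actually measured on the platform.
#' A protein mapping to several measured probesets contributes all of them
#' (as a set union across the pathway's proteins, so a probe shared by two
#' member proteins is counted once); a protein with no probe mapping
#' contributes nothing. The enrichment backgrounds are the measured feature
#' universes: \code{m_G} = all measured probesets, \code{m_M} = all measured
#' non-currency metabolites.
#'
#' @param gene_sets list of gene-namespace membership sets ([read_gmt()]);
#'   members are protein IDs.
#' @param metabolite_sets list of metabolite-namespace membership sets;
#'   members are metabolite names (translated to compound IDs through
#'   \code{id_map$metabolite_to_compound} when provided). A pathway present
#'   in only one file gets empty membership in the other namespace.
#' @param id_map list with \code{protein_to_probes} (named list: protein ID
#'   -> probeset IDs) and optionally \code{metabolite_to_compound} (named
#'   list: metabolite name -> compound ID).
#' @param measured_genes character vector of measured probeset IDs.
#' @param measured_metabolites character vector of measured metabolite
#'   (compound) IDs, before currency removal.
#' @param currency character vector of currency metabolite IDs to exclude;
#'   see [default_currency_metabolites()].
#' @return a `pathway_db` object: list with \code{pathways} (list of
#'   per-pathway records with \code{pathway_id}, \code{name}, \code{source},
#'   \code{gene_members}, \code{probe_members}, \code{metabolite_members},
#'   measured intersections and effective sizes \code{N_G}, \code{N_M}),
#'   backgrounds \code{m_G}, \code{m_M}, the measured universes and the
#'   currency list.
#' @export
build_pathway_db <- function(gene_sets, metabolite_sets,
                             id_map = list(),
                             measured_genes, measured_metabolites,
                             currency = default_currency_metabolites()) {
  .check(length(measured_genes) > 0, "measured gene set is empty")
  .check(length(measured_metabolites) > 0, "measured metabolite set is empty")
  measured_genes <- unique(measured_genes)
  measured_metabolites <- unique(measured_metabolites)

  p2p <- id_map$protein_to_probes
  m2c <- id_map$metabolite_to_compound
  background_mets <- setdiff(measured_metabolites, currency)
  .check(length(background_mets) > 0,
         "currency list removes every metabolite from the background")

  ids <- unique(c(vapply(gene_sets, `[[`, "", "pathway_id"),
                  vapply(metabolite_sets, `[[`, "", "pathway_id")))
  gidx <- stats::setNames(gene_sets,
                          vapply(gene_sets, `[[`, "", "pathway_id"))
  midx <- stats::setNames(metabolite_sets,
                          vapply(metabolite_sets, `[[`, "", "pathway_id"))

  pathways <- lapply(ids, function(id) {
    gs <- gidx[[id]]
    ms <- midx[[id]]
    proteins <- if (is.null(gs)) character(0) else unique(gs$members)
    probes <- if (length(proteins) && !is.null(p2p)) {
      unique(unlist(p2p[intersect(proteins, names(p2p))], use.names = FALSE))
    } else if (length(proteins) && is.null(p2p)) {
      proteins            # members already in probe space
    } else character(0)
    mets <- if (is.null(ms)) character(0) else unique(ms$members)
    if (length(mets) && !is.null(m2c)) {
      mapped <- m2c[intersect(mets, names(m2c))]
      mets <- unique(unlist(mapped, use.names = FALSE))
    }
    mets <- setdiff(mets, currency)
    probe_measured <- intersect(probes, measured_genes)
    met_measured <- intersect(mets, background_mets)
    list(pathway_id = id,
         name = if (!is.null(gs)) gs$name else ms$name,
         source = if (!is.null(gs)) gs$source else ms$source,
         gene_members = proteins,
         probe_members = probes,
         metabolite_members = mets,
         probe_measured = probe_measured,
         met_measured = met_measured,
         N_G = length(probe_measured),
         N_M = length(met_measured))
  })
  names(pathways) <- ids

  structure(list(pathways = pathways,
                 m_G = length(measured_genes),
                 m_M = length(background_mets),
                 measured_genes = measured_genes,
                 measured_metabolites = background_mets,
                 currency = currency),
            class = "pathway_db")
}

#' @export
print.pathway_db <- function(x, ...) {
  el <- eligible_counts(x)
  cat(sprintf(paste0("pathway_db: %d pathways; backgrounds m_G = %d probesets, ",
                     "m_M = %d metabolites\n  %d pathways with >=1 measured gene, ",
                     "%d with >=1 measured metabolite\n  currency excluded: %s\n"),
              length(x$pathways), x$m_G, x$m_M, el[["genes"]], el[["metabolites"]],
              paste(x$currency, collapse = ", ")))
  invisible(x)
}

#' Effective pathway sizes as a data frame
#' @param db a `pathway_db`.
#' @return data.frame with pathway_id, N_G, N_M.
#' @export
effective_sizes <- function(db) {
  data.frame(
    pathway_id = vapply(db$pathways, `[[`, "", "pathway_id"),
    N_G = vapply(db$pathways, `[[`, 0L, "N_G"),
    N_M = vapply(db$pathways, `[[`, 0L, "N_M"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Count pathways eligible in each namespace
#'
#' A pathway is eligible in a namespace when its effective size there is at
#' least one measured feature; the eligible universe sizes feed null model II.
#'
#' @param db a `pathway_db`.
#' @return named integer vector \code{c(genes = ..., metabolites = ...)}.
#' @export
eligible_counts <- function(db) {
  sz <- effective_sizes(db)
  c(genes = sum(sz$N_G >= 1L), metabolites = sum(sz$N_M >= 1L))
}

#' Size of the eligible pathway universe
#'
#' Pathways with at least one measured entity in either namespace; the
#' default universe M for null model II.
#'
#' @param db a `pathway_db`.
#' @return integer count.
#' @export
eligible_universe <- function(db) {
  sz <- effective_sizes(db)
  sum(sz$N_G >= 1L | sz$N_M >= 1L)
}
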