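#' Majority threshold for consensus across D phenotypes
#'
#' floor(D/2) + 1: the smallest strict majority, recovering the "at least
#' 3 of 4 drugs" criterion for a four-drug class.
#'
#' @param n_drugs number of phenotypes in the class.
#' @return integer threshold.
#' @export
majority_threshold <- function(n_drugs) as.integer(floor(n_drugs / 2) + 1L)

#' Build the consensus table across phenotypes of one class
#'
#' Assembles the pathway x drug binary association matrix B, the exact-n
#' histogram (how many pathways are associated with exactly n of the D
#' drugs) and the consensus set: pathways associated with at least
#' \code{threshold} drugs.
#'
#' @param per_drug_sets named list mapping drug ID to its significant
#'   pathway set (character vectors).
#' @param universe character vector of all pathway IDs under consideration;
#'   every set must be contained in it.
#' @param threshold consensus threshold; default [majority_threshold()] of
#'   the number of drugs.
#' @return a `consensus_table`: list with \code{B} (0/1 matrix, pathways x
#'   drugs), \code{exact_n} (named integer vector, n = 1..D),
#'   \code{threshold}, \code{consensus} (pathway IDs with row-sum >=
#'   threshold), \code{n_per_pathway}.
#' @export
build_consensus <- function(per_drug_sets, universe,
                            threshold = majority_threshold(length(per_drug_sets))) {
  drugs <- names(per_drug_sets)
  .check(!is.null(drugs) && !anyDuplicated(drugs), "duplicate or missing drug IDs")
  for (d in drugs) {
    stray <- setdiff(per_drug_sets[[d]], universe)
    .check(length(stray) == 0, "drug %s has pathways outside the universe: %s",
           d, paste(utils::head(stray, 3), collapse = ", "))
  }
  D <- length(drugs)
  B <- vapply(per_drug_sets, function(s) as.integer(universe %in% s),
              integer(length(universe)))
  dim(B) <- c(length(universe), D)
  dimnames(B) <- list(universe, drugs)
  n_per <- rowSums(B)
  exact_n <- vapply(seq_len(D), function(n) sum(n_per == n), 0L)
  names(exact_n) <- as.character(seq_len(D))
  structure(list(B = B,
                 exact_n = exact_n,
                 threshold = as.integer(threshold),
                 consensus = universe[n_per >= threshold],
                 n_per_pathway = stats::setNames(as.integer(n_per), universe)),
            class = "consensus_table")
}

#' @export
print.consensus_table <- function(x, ...) {
  cat(sprintf("consensus_table: %d pathways x %d drugs\n", nrow(x$B), ncol(x$B)))
  cat("  pathways associated with exactly n drugs:\n")
  print(x$exact_n)
  cat(sprintf("  consensus at threshold >= %d: %d pathways\n",
              x$threshold, length(x$consensus)))
  invisible(x)
}

#' Venn partition cell counts for up to five sets
#'
#' Counts the elements carrying each non-empty membership signature (which
#' sets an element belongs to); cells sum to the size of the union.
#'
#' @param sets named list of character vectors (at most 5 sets).
#' @return named integer vector over all 2^D - 1 signatures, named like
#'   \code{"A"}, \code{"A&B"}.
#' @export
venn_partition <- function(sets) {
  D <- length(sets)
  .check(D >= 1 && D <= 5, "venn_partition handles 1..5 sets")
  nm <- names(sets)
  .check(!is.null(nm) && !anyDuplicated(nm), "sets must be uniquely named")
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  dim(member) <- c(length(universe), D)
  sig_of <- apply(member, 1, function(row) paste(nm[row], collapse = "&"))
  combos <- unlist(lapply(seq_len(D), function(k)
    utils::combn(nm, k, paste, collapse = "&", simplify = FALSE)))
  counts <- stats::setNames(integer(length(combos)), combos)
  tab <- table(sig_of)
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Overlap between two pathway sets as a percentage of their union
#'
#' 100 * |a intersect b| / |a union b|, rounded half away from zero to an
#' integer percent. Defined as 0 (with a warning) when both sets are empty.
#'
#' @param set_a,set_b character vectors.
#' @return integer percentage in [0, 100].
#' @export
pairwise_overlap_fraction <- function(set_a, set_b) {
  u <- union(set_a, set_b)
  if (length(u) == 0) {
    warning("both sets empty; overlap reported as 0%", call. = FALSE)
    return(0)
  }
  round_half_up(100 * length(intersect(set_a, set_b)) / length(u))
}

#' Gain of the joint inter-omic consensus over the single-omic consensus
#'
#' Compares the union of the gene-only and metabolite-only consensus sets
#' with the joint-analysis consensus set: how many pathways the joint
#' analysis adds, as a percentage of the single-omic base.
#'
#' @param single_omic_consensus pathway IDs in either single-omic consensus.
#' @param joint_consensus pathway IDs in the joint-analysis consensus.
#' @return list with \code{base}, \code{added}, \code{gain_pct} (NA when the
#'   base is empty).
#' @export
consensus_gain <- function(single_omic_consensus, joint_consensus) {
  base <- length(unique(single_omic_consensus))
  added <- length(setdiff(joint_consensus, single_omic_consensus))
  gain <- if (base == 0) NA_real_ else round_half_up(100 * added / base)
  list(base = base, added = added, gain_pct = gain)
}

#' Direction-consistency of consensus metabolites across a drug class
#'
#' For each metabolite in the consensus metabolic pathways, tabulates per
#' drug whether it was significantly associated and in which direction
#' (sign of r), and flags the metabolite consistent when every significant
#' direction agrees. A metabolite untested for some drug yields a missing
#' cell, which never counts as inconsistent.
#'
#' @param r_table numeric matrix of correlation coefficients, metabolites x
#'   drugs (NA = untested).
#' @param sig_table logical matrix of the same shape: TRUE where the
#'   metabolite passed the FDR cutoff for that drug.
#' @param metabolites optional subset of row names to keep.
#' @return a `direction_panel`: list with \code{r}, \code{significant},
#'   \code{direction} (+1/-1 where significant, NA elsewhere) and
#'   \code{consistent} (named logical; NA when never significant).
#' @export
direction_consistency <- function(r_table, sig_table, metabolites = NULL) {
  .check(all(dim(r_table) == dim(sig_table)), "r and significance tables differ in shape")
  if (!is.null(metabolites)) {
    r_table <- r_table[metabolites, , drop = FALSE]
    sig_table <- sig_table[metabolites, , drop = FALSE]
  }
  sig_table[is.na(sig_table)] <- FALSE
  direction <- ifelse(sig_table, sign(r_table), NA_real_)
  consistent <- apply(direction, 1, function(d) {
    d <- d[!is.na(d)]
    if (length(d) == 0) NA else length(unique(d)) == 1L
  })
  structure(list(r = r_table, significant = sig_table, direction = direction,
                 consistent = consistent),
            class = "direction_panel")
}

#' Validate a held-out test compound against the consensus metabolite panel
#'
#' Counts how many consensus-panel metabolites are significantly correlated
#' with the test compound's sensitivity, and how many of those agree in sign
#' with every training-drug significant direction.
#'
#' @param test_sig named logical vector: significance of each panel
#'   metabolite for the test compound.
#' @param test_r named numeric vector of the test compound's correlations.
#' @param training a `direction_panel` from the training drugs.
#' @return list with \code{n_significant}, \code{panel_size},
#'   \code{n_direction_agree}.
#' @export
validate_test_compound <- function(test_sig, test_r, training) {
  panel <- rownames(training$r)
  .check(length(panel) > 0, "empty consensus metabolite panel")
  .check(all(panel %in% names(test_sig)) && all(panel %in% names(test_r)),
         "test compound results missing for some panel metabolites")
  sig <- which(test_sig[panel])
  agree <- 0L
  for (i in sig) {
    met <- panel[i]
    train_dirs <- training$direction[met, ]
    train_dirs <- train_dirs[!is.na(train_dirs)]
    if (length(train_dirs) == 0 || all(train_dirs == sign(test_r[[met]])))
      agree <- agree + 1L
  }
  list(n_significant = length(sig), panel_size = length(panel),
       n_direction_agree = agree)
}
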