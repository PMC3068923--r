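#' Build the global drug x pathway binary association matrix
#'
#' One row per drug, one column per pathway; an entry is 1 when the joint
#' inter-omic p-value of that pathway is below alpha for that drug. Pathway
#' columns associated with no drug are dropped; drugs with no significant
#' pathway are kept but flagged, and are excluded from clustering.
#'
#' @param enrichments named list (drug ID -> `enrichment_result`), all on
#'   the same pathway universe.
#' @param alpha significance level (default 0.05).
#' @param mode p-value column to threshold, as in [significant_pathways()].
#' @return a `binary_association_matrix`: 0/1 integer matrix (drugs x
#'   pathways) with attributes \code{alpha} and \code{empty_drugs}.
#' @export
build_binary_matrix <- function(enrichments, alpha = 0.05, mode = "joint") {
  .check(!is.null(names(enrichments)), "enrichments must be named by drug")
  universe <- enrichments[[1]]$pathway_id
  for (e in enrichments) {
    .check(identical(e$pathway_id, universe),
           "all drugs must be evaluated on the same pathway universe")
  }
  B <- t(vapply(enrichments, function(e)
    as.integer(universe %in% significant_pathways(e, alpha, mode)),
    integer(length(universe))))
  dimnames(B) <- list(names(enrichments), universe)
  keep <- colSums(B) > 0
  if (!any(keep)) warning("no pathway significant for any drug", call. = FALSE)
  B <- B[, keep, drop = FALSE]
  empty <- rownames(B)[rowSums(B) == 0]
  structure(B, alpha = alpha, empty_drugs = empty,
            class = c("binary_association_matrix", class(B)))
}

#' Hamming distances between the rows of a binary matrix
#'
#' @param m 0/1 matrix.
#' @param normalize divide mismatch counts by the number of columns
#'   (default TRUE, giving the proportion of mismatching positions).
#' @return a `dist` object.
#' @export
hamming_dist <- function(m, normalize = TRUE) {
  storage.mode(m) <- "double"
  d <- stats::dist(m, method = "manhattan")
  if (normalize) d <- d / ncol(m)
  attr(d, "method") <- if (normalize) "hamming" else "hamming_count"
  d
}

#' Complete-linkage hierarchical clustering with a fixed tie-break
#'
#' Agglomerative complete-linkage clustering of the chosen axis of the
#' binary association matrix under the Hamming metric. Ties in the minimum
#' inter-cluster distance are broken by the lowest pair of positions in the
#' current cluster list (a merged cluster inherits the position of its
#' earlier component), so merge order and leaf order are fully
#' deterministic. Drugs with no significant pathway are excluded before
#' clustering.
#'
#' @param matrix a `binary_association_matrix` (or any 0/1 matrix).
#' @param axis cluster the \code{"drugs"} (rows) or \code{"pathways"}
#'   (columns).
#' @param normalize normalise Hamming distances by vector length.
#' @return an object of class \code{hclust} (so \code{plot()},
#'   \code{cutree()} and \code{cophenetic()} apply), with an extra
#'   \code{linkage} element: a data.frame (child1, child2, height, size)
#'   using negative numbers for leaves.
#' @export
cluster_binary <- function(matrix, axis = c("drugs", "pathways"),
                           normalize = TRUE) {
  axis <- match.arg(axis)
  m <- unclass(matrix)
  empty <- attr(matrix, "empty_drugs")
  if (axis == "drugs" && length(empty)) {
    m <- m[setdiff(rownames(m), empty), , drop = FALSE]
  }
  if (axis == "pathways") m <- t(m)
  .check(nrow(m) >= 2, "need at least two %s to cluster", axis)
  d <- hamming_dist(m, normalize = normalize)
  hc <- complete_linkage(d)
  hc$labels <- rownames(m)
  hc$dist.method <- attr(d, "method")
  hc
}

#' Complete-linkage agglomeration on a distance object
#'
#' Classical agglomerative clustering with the complete (maximum) linkage
#' update and a documented deterministic tie-break: among all pairs at the
#' minimum distance, the pair lowest in the current cluster list merges
#' first, and a merged cluster inherits the list position of its earlier
#' component. Output follows the
#' \code{\link[stats]{hclust}} conventions.
#'
#' @param d a `dist` object.
#' @return an \code{hclust}-classed list with \code{merge}, \code{height},
#'   \code{order}, \code{labels}, \code{method}, plus a flat \code{linkage}
#'   table.
#' @export
complete_linkage <- function(d) {
  n <- attr(d, "Size")
  .check(n >= 2, "need at least two items")
  dm <- as.matrix(d)
  diag(dm) <- Inf
  # cluster bookkeeping: id < 0 -> leaf -id; id > 0 -> merge step id
  active_ids <- -(seq_len(n))
  active <- seq_len(n)          # row indices into dm still in play
  members <- as.list(seq_len(n))
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    sub <- dm[active, active, drop = FALSE]
    h <- min(sub)
    idx <- which(sub == h, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    # lowest-index pair first, in cluster creation order
    pick <- idx[order(idx[, 1], idx[, 2])[1], ]
    i <- active[pick[[1]]]; j <- active[pick[[2]]]
    a <- active_ids[i]; b <- active_ids[j]
    merge[step, ] <- sort(c(a, b))
    height[step] <- h
    members[[i]] <- c(members[[i]], members[[j]])
    # complete linkage: distance to merged cluster is the max of distances
    newd <- pmax(dm[i, ], dm[j, ])
    dm[i, ] <- newd; dm[, i] <- newd
    dm[i, i] <- Inf
    active_ids[i] <- step
    active <- setdiff(active, j)
  }

  order <- .hclust_leaf_order(merge, n)
  hc <- structure(list(merge = merge, height = height, order = order,
                       labels = NULL, method = "complete",
                       call = match.call(),
                       linkage = data.frame(child1 = merge[, 1],
                                            child2 = merge[, 2],
                                            height = height,
                                            size = .merge_sizes(merge))),
                  class = "hclust")
  hc
}

.merge_sizes <- function(merge) {
  n <- nrow(merge) + 1L
  size <- integer(nrow(merge))
  for (s in seq_len(nrow(merge))) {
    size[s] <- sum(vapply(merge[s, ], function(ch)
      if (ch < 0) 1L else size[ch], 0L))
  }
  size
}

.hclust_leaf_order <- function(merge, n) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(n - 1L)
}

#' Most frequently associated pathways, including ties
#'
#' Ranks pathways by the number of drugs they are associated with (column
#' sums of the binary matrix) and returns the top \code{top_k}, extended to
#' include every pathway tied with the k-th.
#'
#' @param matrix a `binary_association_matrix`.
#' @param top_k nominal list length (default 50).
#' @return data.frame with \code{pathway_id} and \code{n_drugs}, sorted by
#'   frequency (descending), ties broken by pathway ID for stable output.
#' @export
frequent_pathways <- function(matrix, top_k = 50L) {
  .check(top_k >= 1, "top_k must be >= 1")
  counts <- colSums(unclass(matrix))
  ord <- order(-counts, names(counts))
  counts <- counts[ord]
  k <- min(top_k, length(counts))
  cutoff <- counts[[k]]
  keep <- counts >= cutoff
  data.frame(pathway_id = names(counts)[keep],
             n_drugs = as.integer(counts[keep]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare a consensus set with the globally frequent pathways
#'
#' Specificity screen: consensus pathways that are *not* among the most
#' frequently drug-associated pathways are candidates for class-specific
#' sensitivity mechanisms.
#'
#' @param consensus_set character vector of consensus pathway IDs.
#' @param frequent_set character vector of frequent pathway IDs (e.g.
#'   \code{frequent_pathways(B)$pathway_id}).
#' @return list with \code{n_intersect}, \code{n_consensus_only},
#'   \code{intersect}, \code{consensus_only}.
#' @export
specificity_compare <- function(consensus_set, frequent_set) {
  both <- intersect(consensus_set, frequent_set)
  only <- setdiff(consensus_set, frequent_set)
  list(n_intersect = length(both), n_consensus_only = length(only),
       intersect = both, consensus_only = only)
}
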