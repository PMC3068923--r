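#' Null model I: random feature lists of matching size
#'
#' Estimates the consensus expected under a null in which each drug's
#' significant gene and metabolite panels are replaced by uniform draws
#' (without replacement) from the measured backgrounds, keeping the observed
#' panel sizes. Each replicate runs the full joint inter-omic enrichment and
#' consensus counting; the report is the mean exact-n histogram over
#' replicates. This is a null of the joint analysis: gene and metabolite
#' lists are drawn independently per drug.
#'
#' @param db a `pathway_db`.
#' @param panel_sizes data.frame with columns \code{drug_id},
#'   \code{n_genes}, \code{n_metabolites}: the per-drug panel sizes to match.
#' @param R number of replicates (default 100).
#' @param alpha pathway significance level for the joint p (default 0.05).
#' @param seed integer seed; all replicate draws flow from it.
#' @return a `null_report`: list with \code{model = "I"},
#'   \code{expected_exact_n} (mean counts, n = 1..D), \code{replicates},
#'   \code{seed}, \code{per_replicate} (R x D matrix of exact-n counts).
#' @export
null_model_I <- function(db, panel_sizes, R = 100, alpha = 0.05, seed = 1L) {
  .check(all(c("drug_id", "n_genes", "n_metabolites") %in% names(panel_sizes)),
         "panel_sizes needs columns drug_id, n_genes, n_metabolites")
  .check(all(panel_sizes$n_genes <= db$m_G),
         "gene panel size exceeds background")
  .check(all(panel_sizes$n_metabolites <= db$m_M),
         "metabolite panel size exceeds background")
  .check(R >= 1, "R must be >= 1")
  D <- nrow(panel_sizes)
  universe <- names(db$pathways)

  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(.derive_seed(seed, "null_model"))

  per_rep <- matrix(0L, nrow = R, ncol = D,
                    dimnames = list(NULL, as.character(seq_len(D))))
  for (r in seq_len(R)) {
    sets <- lapply(seq_len(D), function(i) {
      gp <- structure(list(drug_id = panel_sizes$drug_id[i], namespace = "gene",
                           selected = sample(db$measured_genes,
                                             panel_sizes$n_genes[i])),
                      class = "feature_panel")
      mp <- structure(list(drug_id = panel_sizes$drug_id[i],
                           namespace = "metabolite",
                           selected = sample(db$measured_metabolites,
                                             panel_sizes$n_metabolites[i])),
                      class = "feature_panel")
      significant_pathways(enrich_joint(gp, mp, db, alpha), alpha, "joint")
    })
    names(sets) <- panel_sizes$drug_id
    per_rep[r, ] <- build_consensus(sets, universe)$exact_n
  }
  structure(list(model = "I",
                 expected_exact_n = stats::setNames(colMeans(per_rep),
                                                    colnames(per_rep)),
                 replicates = R, alpha = alpha, seed = seed,
                 per_replicate = per_rep),
            class = "null_report")
}

#' Null model II: random pathway selection (exact Poisson-binomial)
#'
#' Assumes each drug selects its significant pathways uniformly at random
#' from the eligible universe of M pathways, so a given pathway is selected
#' by drug d with probability q_d = S_d / M independently across drugs. The
#' number of drugs selecting a pathway is then Poisson-binomial; the
#' expected count of pathways selected by exactly n drugs is M * P(n),
#' computed exactly by polynomial convolution over the drugs.
#'
#' @param per_drug_counts named integer vector S_d: significant-pathway
#'   counts per drug.
#' @param M eligible pathway universe size (see [eligible_universe()]).
#' @return a `null_report`: list with \code{model = "II"},
#'   \code{expected_exact_n} (n = 1..D), \code{expected_n0} (expected count
#'   selected by no drug), \code{prob_exact_n} (P(n), n = 0..D).
#' @export
null_model_II <- function(per_drug_counts, M) {
  .check(M > 0, "eligible universe size M must be positive")
  .check(all(per_drug_counts >= 0) && all(per_drug_counts <= M),
         "per-drug counts must lie in [0, M]")
  q <- per_drug_counts / M
  # P(n) via polynomial convolution: product over drugs of (1-q_d + q_d z)
  pmf <- 1
  for (qd in q) pmf <- c(pmf * (1 - qd), 0) + c(0, pmf * qd)
  D <- length(q)
  names(pmf) <- as.character(0:D)
  expected <- M * pmf
  structure(list(model = "II",
                 expected_exact_n = expected[-1],
                 expected_n0 = expected[[1]],
                 prob_exact_n = pmf,
                 M = M, per_drug_counts = per_drug_counts),
            class = "null_report")
}

#' Cumulative false discovery rate over consensus thresholds
#'
#' For each threshold n, the FDR is the null-expected number of pathways
#' associated with at least n drugs divided by the observed number, as a
#' percentage: FDR(n) = 100 * sum_{j >= n} expected_j / sum_{j >= n}
#' observed_j. Reported to one decimal (half away from zero) and capped at
#' 100. A threshold with zero observed cumulative count is undefined and
#' reported as NA.
#'
#' @param observed exact-n counts from the real data (n = n_min, n_min+1, ...).
#' @param expected exact-n counts from a null model, aligned with
#'   \code{observed}.
#' @param n_min the n-value of the first entry (default 1).
#' @return data.frame with columns \code{n}, \code{observed_cum},
#'   \code{expected_cum}, \code{fdr_pct}.
#' @export
cumulative_fdr <- function(observed, expected, n_min = 1L) {
  .check(length(observed) == length(expected),
         "observed and expected lengths differ")
  obs_cum <- rev(cumsum(rev(observed)))
  exp_cum <- rev(cumsum(rev(expected)))
  fdr <- ifelse(obs_cum > 0,
                pmin(100, round_half_up(100 * exp_cum / obs_cum, 1)),
                NA_real_)
  if (any(obs_cum == 0)) {
    warning("zero observed cumulative count at some thresholds; FDR undefined there",
            call. = FALSE)
  }
  data.frame(n = seq(n_min, length.out = length(observed)),
             observed_cum = obs_cum, expected_cum = exp_cum, fdr_pct = fdr,
             row.names = NULL)
}

#' Permutation test of the joint-analysis gain for one drug
#'
#' Breaks the pathway-level coupling between the gene and metabolite
#' analyses: the metabolite p-value list is permuted across pathways P
#' times, the joint significant-pathway count is recomputed for each
#' permutation, and the number of permutations yielding strictly more
#' significant pathways than the real (unpermuted) data is recorded. The
#' empirical p-value is exceedance / P; \code{corrected} gives the
#' (exceedance + 1) / (P + 1) variant.
#'
#' @param p_G,p_M aligned per-pathway p-value vectors for one drug.
#' @param alpha joint significance level (default 0.05).
#' @param P number of permutations (default 100).
#' @param seed integer seed.
#' @param method joint combination method passed to [combine_joint()].
#' @return list with \code{real_count}, \code{exceedance}, \code{P},
#'   \code{empirical_p}, \code{corrected}, \code{perm_counts}.
#' @export
permutation_gain_test <- function(p_G, p_M, alpha = 0.05, P = 100, seed = 1L,
                                  method = "product") {
  .check(length(p_G) == length(p_M), "p_G and p_M lengths differ")
  .check(P >= 1, "P must be >= 1")
  real_count <- sum(combine_joint(p_G, p_M, method) < alpha)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(.derive_seed(seed, "permutation"))
  perm_counts <- vapply(seq_len(P), function(i) {
    sum(combine_joint(p_G, sample(p_M), method) < alpha)
  }, 0L)
  exceed <- sum(perm_counts > real_count)
  list(real_count = real_count, exceedance = exceed, P = P,
       empirical_p = exceed / P, corrected = (exceed + 1) / (P + 1),
       perm_counts = perm_counts)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
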