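#' Correlate every feature to a drug-sensitivity phenotype
#'
#' Computes the Pearson correlation between each feature's abundance and the
#' per-sample -log(GI50) phenotype over pairwise-complete observations, with
#' the two-sided p-value from the t transform r * sqrt((n-2)/(1-r^2)) on
#' n - 2 degrees of freedom. Features with fewer than three complete pairs
#' or zero variance over the paired samples cannot be tested: they are kept
#' in the table but flagged \code{excluded}, so they can never enter a
#' significant panel.
#'
#' @param matrix an `omics_matrix` (features x samples).
#' @param phenotype named numeric vector of replicate-averaged -log(GI50)
#'   values; names are sample IDs and are matched against the matrix columns.
#' @param min_pairs minimum complete pairs required to test a feature.
#' @return an `association_table` data.frame with columns \code{feature_id},
#'   \code{r}, \code{p}, \code{n_used}, \code{excluded}; attributes record
#'   the namespace.
#' @export
correlate <- function(matrix, phenotype, min_pairs = 3L) {
  shared <- intersect(colnames(matrix), names(phenotype))
  .check(length(shared) >= min_pairs,
         "only %d shared samples between matrix and phenotype", length(shared))
  m <- matrix[, shared, drop = FALSE]
  y <- as.numeric(phenotype[shared])

  ok_y <- !is.na(y)
  pair_ok <- !is.na(m) & rep(ok_y, each = nrow(m))
  n_used <- rowSums(pair_ok)

  r <- suppressWarnings(
    as.numeric(stats::cor(t(m), y, use = "pairwise.complete.obs"))
  )
  r <- pmin(1, pmax(-1, r))
  few <- n_used < min_pairs
  zero_var <- !few & is.na(r)          # sd == 0 over the paired samples
  excluded <- few | zero_var
  if (any(few)) {
    warning(sprintf("%d feature(s) with fewer than %d complete pairs excluded",
                    sum(few), min_pairs), call. = FALSE)
  }

  tt <- r * sqrt(pmax(n_used - 2, 0) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = pmax(n_used - 2, 1))
  p <- pmin(1, pmax(p, .Machine$double.xmin))
  p[excluded] <- NA_real_
  r[excluded] <- NA_real_

  structure(
    data.frame(feature_id = rownames(m), r = r, p = p,
               n_used = as.integer(n_used), excluded = excluded,
               row.names = NULL, stringsAsFactors = FALSE),
    namespace = attr(matrix, "namespace"),
    class = c("association_table", "data.frame")
  )
}

#' Select a significant feature panel at an FDR threshold
#'
#' Applies the Benjamini-Hochberg step-up procedure to the two-sided
#' correlation p-values and retains features significant at FDR \code{fdr_q}
#' (default 60\%: a deliberately permissive threshold so that downstream
#' pathway over-representation is adequately powered). Each selected feature
#' carries the sign of its correlation. Excluded (untestable) features never
#' enter the panel; an empty panel is a valid result.
#'
#' @param assoc an `association_table` from [correlate()].
#' @param fdr_q FDR threshold in (0, 1); default 0.60.
#' @param drug_id optional drug label stored on the panel.
#' @return a `feature_panel`: list with \code{drug_id}, \code{namespace},
#'   \code{fdr_q}, \code{selected} (character vector of feature IDs),
#'   \code{sign} (named -1/+1 vector over selected), \code{n_tested}.
#' @export
select_significant <- function(assoc, fdr_q = 0.60, drug_id = NA_character_) {
  .check(is.numeric(fdr_q) && fdr_q > 0 && fdr_q < 1,
         "fdr_q must be in (0, 1)")
  testable <- !assoc$excluded
  q_adj <- rep(NA_real_, nrow(assoc))
  q_adj[testable] <- stats::p.adjust(assoc$p[testable], method = "BH")
  sel <- which(testable & q_adj <= fdr_q)
  structure(list(drug_id = drug_id,
                 namespace = attr(assoc, "namespace"),
                 fdr_q = fdr_q,
                 selected = assoc$feature_id[sel],
                 sign = stats::setNames(sign(assoc$r[sel]),
                                        assoc$feature_id[sel]),
                 n_tested = sum(testable)),
            class = "feature_panel")
}

#' @export
print.feature_panel <- function(x, ...) {
  cat(sprintf("feature_panel [%s%s]: %d of %d features selected at FDR %.0f%%\n",
              if (is.na(x$drug_id)) "" else paste0(x$drug_id, ", "),
              x$namespace %||% "?", length(x$selected), x$n_tested,
              100 * x$fdr_q))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an association table with selection flags as TSV
#' @param assoc `association_table`.
#' @param panel `feature_panel` from the same table.
#' @param path output path.
#' @export
write_association_table <- function(assoc, panel, path) {
  df <- as.data.frame(assoc)
  df$selected <- df$feature_id %in% panel$selected
  df$sign <- ifelse(df$selected, sign(df$r), NA_real_)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
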