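#' Published platinum-drug metabolite correlation panel
#'
#' The 22 metabolites appearing in the consensus platinum-sensitivity
#' metabolic pathways from the NCI60 panel, with their Pearson correlations
#' to -log(GI50) for four training platinum drugs (carboplatin, cisplatin,
#' iproplatin, tetraplatin) and the held-out test compound
#' diaminocyclohexyl-Pt(II), plus a flag for whether each association
#' passed the 60% FDR feature-selection cutoff. Useful as a worked example
#' for [direction_consistency()] and [validate_test_compound()].
#'
#' @param training_drugs column prefixes treated as the training class.
#' @param test_drug column prefix of the held-out compound.
#' @return list with \code{r} (22 x 5 numeric matrix),
#'   \code{significant} (logical matrix of the same shape),
#'   \code{training_drugs}, \code{test_drug}.
#' @export
platinum_metabolite_panel <- function(
    training_drugs = c("carboplatin", "cisplatin", "iproplatin", "tetraplatin"),
    test_drug = "diaminocyclohexyl_Pt_II") {
  path <- system.file("extdata", "platinum_metabolite_panel.tsv",
                      package = "consensusOR", mustWork = TRUE)
  df <- utils::read.delim(path, check.names = FALSE)
  drugs <- c(training_drugs, test_drug)
  r <- as.matrix(df[paste0(drugs, "_r")])
  sig <- as.matrix(df[paste0(drugs, "_sig")])
  dimnames(r) <- dimnames(sig) <- list(df$metabolite, drugs)
  list(r = r, significant = sig,
       training_drugs = training_drugs, test_drug = test_drug)
}
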