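# Small fixtures built in code.

mset <- function(id, members, namespace = "gene", name = id,
                 source = "test") {
  list(pathway_id = id, name = name, source = source,
       members = members, namespace = namespace)
}

# tiny two-namespace database: 3 proteins expanding to probes, 4 pathways
tiny_db <- function(currency = character(0)) {
  gene_sets <- list(
    mset("PW1", c("PA", "PB")),
    mset("PW2", c("PC")),
    mset("PW3", c("PA", "PC"))
  )
  met_sets <- list(
    mset("PW1", c("metX", "metY"), "metabolite"),
    mset("PW4", c("metZ"), "metabolite")
  )
  id_map <- list(
    protein_to_probes = list(PA = c("g1", "g2", "g3"), PB = "g4"),
    metabolite_to_compound = list(metX = "cX", metY = "cY", metZ = "cZ")
  )
  build_pathway_db(gene_sets, met_sets, id_map,
                   measured_genes = paste0("g", 1:10),
                   measured_metabolites = c("cX", "cY", "cZ", "cW"),
                   currency = currency)
}

panel_of <- function(features, namespace = "gene", drug = "d1") {
  structure(list(drug_id = drug, namespace = namespace, fdr_q = 0.6,
                 selected = features,
                 sign = stats::setNames(rep(1, length(features)), features),
                 n_tested = NA_integer_),
            class = "feature_panel")
}

# a fast small synthetic configuration for structural tests
small_config <- function(seed = 1L,
                         plan = c(gene_signal = 3L, metabolite_signal = 2L,
                                  split_signal = 3L),
                         ...) {
  synthetic_config(n_samples = 40L, n_genes = 400L, n_metabolites = 60L,
                   n_pathways = 60L, plan = plan, seed = seed, ...)
}

# fabricate per-drug pathway sets realising given exact-n counts
sets_with_exact_n <- function(exact_n, drugs = paste0("d", seq_along(exact_n))) {
  D <- length(drugs)
  sets <- stats::setNames(rep(list(character(0)), D), drugs)
  universe <- character(0)
  idx <- 0
  for (n in seq_len(D)) {
    for (i in seq_len(exact_n[n])) {
      idx <- idx + 1
      pw <- sprintf("PW%04d", idx)
      universe <- c(universe, pw)
      # rotate which drugs carry the pathway so sets differ
      for (d in ((seq_len(n) + i) %% D) + 1) {
        sets[[d]] <- c(sets[[d]], pw)
      }
    }
  }
  list(sets = sets, universe = universe)
}
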