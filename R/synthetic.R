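#' Configuration for the synthetic multi-omic panel generator
#'
#' Describes an NCI60-like study: a panel of cell-line samples profiled on
#' a gene-expression platform and a metabolite assay, with per-drug
#' -log(GI50) sensitivity phenotypes organised in drug classes, and a
#' two-namespace pathway database in which a chosen number of pathways per
#' class carry planted signal. Defaults emulate the real panel's shape (58
#' samples, 154 identified metabolites, 4 training drugs per class plus an
#' optional held-out test drug) at a desk-scale gene universe.
#'
#' Planted pathway labels: \code{gene_signal} pathways load only their gene
#' members on the class latent, \code{metabolite_signal} only their
#' metabolite members, and \code{split_signal} pathways load both namespaces
#' weakly — calibrated so that each single-omic enrichment p typically
#' falls in (0.05, 0.3) while the joint product falls below 0.05, the
#' regime in which inter-omic combination pays off. All remaining pathways
#' are null.
#'
#' @param n_samples number of cell lines (default 58).
#' @param n_genes number of measured probesets (default 2000).
#' @param n_metabolites number of measured, identified metabolites
#'   (default 154), excluding the currency metabolites which the generator
#'   adds on top.
#' @param n_pathways pathway count in the database (default 200).
#' @param n_drug_classes number of drug classes (default 1).
#' @param drugs_per_class training drugs per class (default 4).
#' @param test_drug add one held-out drug to class 1 (default FALSE).
#' @param plan named vector: planted pathways per class, with entries
#'   \code{gene_signal}, \code{metabolite_signal}, \code{split_signal}.
#' @param rho latent loading of fully planted signal features (default 0.5,
#'   giving feature-latent correlations of rho/sqrt(1+rho^2) ~ 0.45).
#' @param rho_split loadings for split-signal members, a named vector
#'   \code{c(gene = ..., metabolite = ...)} (a single number is used for
#'   both); \code{NULL} (default) calibrates them per namespace by pilot
#'   simulation at generation time.
#' @param signal_fraction fraction of a planted pathway's measured members
#'   that carry signal (default 0.6).
#' @param drug_noise sd of the per-drug noise around the class latent
#'   (default 0.5).
#' @param gene_set_range,met_set_range pathway membership size ranges
#'   (proteins, metabolites).
#' @param p_gene_membership,p_met_membership probability that a pathway has
#'   members in each namespace (every pathway gets at least one namespace).
#' @param seed master seed; every stream derives from it.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_samples = 58L, n_genes = 2000L,
                             n_metabolites = 154L, n_pathways = 200L,
                             n_drug_classes = 1L, drugs_per_class = 4L,
                             test_drug = FALSE,
                             plan = c(gene_signal = 5L, metabolite_signal = 4L,
                                      split_signal = 6L),
                             rho = 0.5, rho_split = NULL,
                             signal_fraction = 0.6, drug_noise = 0.5,
                             gene_set_range = c(5L, 40L),
                             met_set_range = c(2L, 12L),
                             p_gene_membership = 0.9, p_met_membership = 0.35,
                             seed = 1L) {
  cfg <- list(n_samples = n_samples, n_genes = n_genes,
              n_metabolites = n_metabolites, n_pathways = n_pathways,
              n_drug_classes = n_drug_classes,
              drugs_per_class = drugs_per_class, test_drug = test_drug,
              plan = plan, rho = rho, rho_split = rho_split,
              signal_fraction = signal_fraction, drug_noise = drug_noise,
              gene_set_range = gene_set_range, met_set_range = met_set_range,
              p_gene_membership = p_gene_membership,
              p_met_membership = p_met_membership, seed = seed)
  .check(all(c(n_samples, n_genes, n_metabolites, n_pathways,
               n_drug_classes, drugs_per_class) > 0), "counts must be positive")
  .check(rho >= 0 && rho < 1, "rho must be in [0, 1)")
  .check(sum(plan) * n_drug_classes <= n_pathways,
         "planted pathway plan exceeds the pathway count")
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic multi-omic drug-sensitivity panel
#'
#' Builds the pathway database structure (membership, ID maps, currency
#' metabolites), plants signal per the configuration plan, and simulates
#' abundance matrices and phenotypes. The signal model is additive
#' Gaussian: each class has a latent per-sample sensitivity vector L;
#' drugs in the class observe L plus independent noise, and each signal
#' feature is rho * L plus unit noise. Truth labels are emitted alongside
#' the data and are never consumed by the analysis pipeline.
#'
#' @param config a [synthetic_config()].
#' @param write_dir optional directory; when given, every input is also
#'   written in the pipeline's file dialects (TSV matrices and phenotypes,
#'   two GMT files, ID-map TSVs, measured-feature lists, truth JSON).
#' @return a `synthetic_bundle`: list with \code{gene} and
#'   \code{metabolite} omics matrices, \code{phenotypes} (named list),
#'   \code{drug_classes} (named character), \code{db} (a `pathway_db`),
#'   \code{sets} (the raw membership sets and ID maps), \code{truth}
#'   (pathway labels, planted features, calibrated loadings) and
#'   \code{config}.
#' @export
generate_synthetic <- function(config, write_dir = NULL) {
  old <- .save_rng()
  on.exit(.restore_rng(old))

  set.seed(.derive_seed(config$seed, "generate"))
  structure_ <- .synth_structure(config)

  rho_split <- config$rho_split
  if (is.null(rho_split)) {
    rho_split <- if (any(structure_$truth$label == "split_signal")) {
      .calibrate_split_rho(config, structure_)
    } else c(gene = NA_real_, metabolite = NA_real_)
  }
  if (length(rho_split) == 1L) {
    rho_split <- c(gene = unname(rho_split), metabolite = unname(rho_split))
  }

  set.seed(.derive_seed(config$seed, "generate") + 1L)
  data <- .synth_matrices(config, structure_, rho_split)

  truth <- structure_$truth
  has_g <- truth$label %in% c("gene_signal", "split_signal")
  has_m <- truth$label %in% c("metabolite_signal", "split_signal")
  truth$rho_gene <- ifelse(truth$label == "split_signal",
                           rho_split[["gene"]],
                           ifelse(has_g, config$rho, 0))
  truth$rho_metabolite <- ifelse(truth$label == "split_signal",
                                 rho_split[["metabolite"]],
                                 ifelse(has_m, config$rho, 0))
  bundle <- structure(list(gene = data$gene, metabolite = data$metabolite,
                           phenotypes = data$phenotypes,
                           drug_classes = data$drug_classes,
                           db = structure_$db, sets = structure_$sets,
                           truth = truth,
                           signal_features = structure_$signal_features,
                           latents = data$latents,   # truth-side only
                           rho_split = rho_split,
                           config = config),
                      class = "synthetic_bundle")
  if (!is.null(write_dir)) write_synthetic(bundle, write_dir)
  bundle
}

# sample the pathway database structure and the planted-pathway assignment
.synth_structure <- function(config) {
  probes <- sprintf("G%05d", seq_len(config$n_genes))
  # partition probes among proteins in blocks of 1..3 (probe expansion)
  p2p <- list(); i <- 1L; prot <- 0L
  while (i <= config$n_genes) {
    prot <- prot + 1L
    k <- min(sample(1:3, 1), config$n_genes - i + 1L)
    p2p[[sprintf("PR%05d", prot)]] <- probes[i:(i + k - 1L)]
    i <- i + k
  }
  proteins <- names(p2p)

  currency <- default_currency_metabolites()
  n_reg <- config$n_metabolites - length(currency)
  .check(n_reg > 0, "n_metabolites must exceed the currency list length")
  met_names <- sprintf("met_%03d", seq_len(n_reg))
  compounds <- sprintf("C%05d", seq_len(n_reg))
  m2c <- as.list(stats::setNames(compounds, met_names))
  m2c[currency] <- paste0("CUR", seq_along(currency))
  # the measured assay covers the currency metabolites too; they are
  # stripped again at analysis time, as on the real platform
  measured_mets <- c(compounds, unlist(m2c[currency], use.names = FALSE))

  ids <- sprintf("PW%04d", seq_len(config$n_pathways))
  has_gene <- stats::runif(config$n_pathways) < config$p_gene_membership
  has_met <- stats::runif(config$n_pathways) < config$p_met_membership
  none <- !has_gene & !has_met
  has_gene[none] <- TRUE

  gene_sets <- list(); met_sets <- list()
  for (j in seq_len(config$n_pathways)) {
    if (has_gene[j]) {
      sz <- sample(config$gene_set_range[1]:config$gene_set_range[2], 1)
      gene_sets[[length(gene_sets) + 1L]] <-
        list(pathway_id = ids[j], name = ids[j], source = "synthetic",
             members = sample(proteins, min(sz, length(proteins))),
             namespace = "gene")
    }
    if (has_met[j]) {
      sz <- sample(config$met_set_range[1]:config$met_set_range[2], 1)
      members <- sample(met_names, min(sz, length(met_names)))
      # sprinkle currency metabolites into ~20% of metabolite pathways
      if (stats::runif(1) < 0.2) members <- c(members, sample(currency, 1))
      met_sets[[length(met_sets) + 1L]] <-
        list(pathway_id = ids[j], name = ids[j], source = "synthetic",
             members = unique(members), namespace = "metabolite")
    }
  }

  db <- build_pathway_db(gene_sets, met_sets,
                         id_map = list(protein_to_probes = p2p,
                                       metabolite_to_compound = m2c),
                         measured_genes = probes,
                         measured_metabolites = measured_mets,
                         currency = unlist(m2c[currency], use.names = FALSE))

  sz <- effective_sizes(db)
  # planted pathways need enough measured members to carry detectable signal
  elig <- list(
    gene_signal = sz$pathway_id[sz$N_G >= 8],
    metabolite_signal = sz$pathway_id[sz$N_M >= 3],
    # split pathways need sizeable membership in both namespaces so their
    # enrichment p-values are stable enough to calibrate into a band
    split_signal = sz$pathway_id[sz$N_G >= 15 & sz$N_M >= 5]
  )
  truth <- data.frame(pathway_id = sz$pathway_id, label = "null",
                      class = NA_integer_, stringsAsFactors = FALSE)
  taken <- character(0)
  for (cl in seq_len(config$n_drug_classes)) {
    for (lab in names(config$plan)) {
      need <- config$plan[[lab]]
      pool <- setdiff(elig[[lab]], taken)
      .check(length(pool) >= need,
             "not enough eligible pathways to plant %d of label %s", need, lab)
      pick <- sample(pool, need)
      taken <- c(taken, pick)
      truth$label[truth$pathway_id %in% pick] <- lab
      truth$class[truth$pathway_id %in% pick] <- cl
    }
  }

  # choose the signal-carrying members of each planted pathway now, so the
  # same features are used at every candidate split loading
  signal_features <- list(gene = list(), metabolite = list())
  for (r in which(truth$label != "null")) {
    pw <- db$pathways[[truth$pathway_id[r]]]
    lab <- truth$label[r]
    pick_frac <- function(v) {
      n <- max(1L, round(config$signal_fraction * length(v)))
      sample(v, n)
    }
    if (lab %in% c("gene_signal", "split_signal")) {
      signal_features$gene[[pw$pathway_id]] <- pick_frac(pw$probe_measured)
    }
    if (lab %in% c("metabolite_signal", "split_signal")) {
      signal_features$metabolite[[pw$pathway_id]] <- pick_frac(pw$met_measured)
    }
  }

  list(db = db, truth = truth, signal_features = signal_features,
       sets = list(gene_sets = gene_sets, met_sets = met_sets,
                   protein_to_probes = p2p, metabolite_to_compound = m2c,
                   measured_genes = probes,
                   measured_metabolites = measured_mets,
                   currency_compounds = unlist(m2c[currency], use.names = FALSE)))
}

# simulate matrices and phenotypes for a fixed structure and split loading
.synth_matrices <- function(config, structure_, rho_split) {
  n <- config$n_samples
  samples <- sprintf("CL%02d", seq_len(n))
  latents <- lapply(seq_len(config$n_drug_classes), function(cl)
    stats::rnorm(n))

  phenotypes <- list(); drug_classes <- character(0)
  for (cl in seq_len(config$n_drug_classes)) {
    nd <- config$drugs_per_class + (config$test_drug && cl == 1L)
    for (d in seq_len(nd)) {
      id <- sprintf("class%d_drug%d", cl, d)
      if (config$test_drug && cl == 1L && d == nd) id <- "class1_test"
      phenotypes[[id]] <- stats::setNames(
        latents[[cl]] + config$drug_noise * stats::rnorm(n), samples)
      drug_classes[id] <- cl
    }
  }

  gene_m <- matrix(stats::rnorm(config$n_genes * n), ncol = n,
                   dimnames = list(structure_$sets$measured_genes, samples))
  mets <- structure_$sets$measured_metabolites
  met_m <- matrix(stats::rnorm(length(mets) * n), ncol = n,
                  dimnames = list(mets, samples))

  truth <- structure_$truth
  for (r in which(truth$label != "null")) {
    id <- truth$pathway_id[r]
    L <- latents[[truth$class[r]]]
    split <- truth$label[r] == "split_signal"
    rho_g <- if (split) rho_split[["gene"]] else config$rho
    rho_m <- if (split) rho_split[["metabolite"]] else config$rho
    gf <- structure_$signal_features$gene[[id]]
    if (length(gf)) gene_m[gf, ] <- gene_m[gf, ] +
        matrix(rho_g * L, nrow = length(gf), ncol = n, byrow = TRUE)
    mf <- structure_$signal_features$metabolite[[id]]
    if (length(mf)) met_m[mf, ] <- met_m[mf, ] +
        matrix(rho_m * L, nrow = length(mf), ncol = n, byrow = TRUE)
  }

  list(gene = omics_matrix(gene_m, "gene"),
       metabolite = omics_matrix(met_m, "metabolite"),
       phenotypes = phenotypes, drug_classes = drug_classes,
       latents = latents)
}

# pilot calibration of the split-signal loadings, one per namespace: for
# each namespace, pick the grid value whose median single-omic enrichment p
# for the split pathways (over pilot replicates) is closest to 0.12, the
# geometric centre of the (0.05, 0.3) target band. The namespaces differ
# greatly in power (pathways have many measured probes but few measured
# metabolites), so a shared loading cannot put both sides in the band.
.calibrate_split_rho <- function(config, structure_,
                                 grid = seq(0.04, 0.60, by = 0.02),
                                 n_pilot = 3L) {
  split_ids <- structure_$truth$pathway_id[structure_$truth$label == "split_signal"]
  target <- sqrt(0.05 * 0.3)
  db <- structure_$db

  pilot_p <- function(rho_pair) {
    lapply(seq_len(n_pilot), function(rep) {
      set.seed(.derive_seed(config$seed, "pilot") + rep * 131L +
                 round(1000 * rho_pair[["gene"]]) +
                 round(999983 * rho_pair[["metabolite"]]))
      data <- .synth_matrices(config, structure_, rho_pair)
      d1 <- names(data$phenotypes)[1]
      gm <- data$gene[rownames(data$gene) %in% db$measured_genes, ]
      mm <- data$metabolite[rownames(data$metabolite) %in%
                              db$measured_metabolites, ]
      gp <- select_significant(correlate(gm, data$phenotypes[[d1]]),
                               drug_id = d1)
      mp <- select_significant(correlate(mm, data$phenotypes[[d1]]),
                               drug_id = d1)
      res <- enrich_joint(gp, mp, db)
      rows <- res$pathway_id %in% split_ids
      list(gene = res$p_G[rows], metabolite = res$p_M[rows])
    })
  }
  band_score <- function(ps) abs(log(stats::median(ps)) - log(target))

  # calibrate each namespace in turn, holding the other at mid-grid
  rho <- c(gene = stats::median(grid), metabolite = stats::median(grid))
  for (ns in c("gene", "metabolite")) {
    score <- vapply(grid, function(g) {
      cand <- rho; cand[[ns]] <- g
      band_score(unlist(lapply(pilot_p(cand), `[[`, ns)))
    }, 0)
    rho[[ns]] <- grid[which.min(score)]
  }
  rho
}

#' Write a synthetic bundle in the pipeline's file dialects
#'
#' @param bundle a `synthetic_bundle`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_synthetic <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_omics_matrix(bundle$gene, fp("genes.tsv"))
  write_omics_matrix(bundle$metabolite, fp("metabolites.tsv"))
  write_phenotypes(bundle$phenotypes, fp("phenotypes.tsv"))
  write_gmt(bundle$sets$gene_sets, fp("pathways_gene.gmt"))
  write_gmt(bundle$sets$met_sets, fp("pathways_metabolite.gmt"))
  write_id_map(bundle$sets$protein_to_probes, fp("id_map_protein_probe.tsv"))
  write_id_map(bundle$sets$metabolite_to_compound,
               fp("id_map_metabolite_compound.tsv"))
  writeLines(bundle$sets$measured_genes, fp("measured_genes.txt"))
  writeLines(bundle$sets$measured_metabolites, fp("measured_metabolites.txt"))
  writeLines(bundle$sets$currency_compounds, fp("currency.txt"))
  truth <- list(pathways = bundle$truth,
                rho_split = bundle$rho_split,
                drug_classes = as.list(bundle$drug_classes),
                signal_features = bundle$signal_features,
                currency_compounds = bundle$sets$currency_compounds)
  jsonlite::write_json(truth, fp("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Score consensus recovery of planted pathways against the truth
#'
#' Compares the consensus sets of a pipeline run on synthetic data with the
#' generator's planted labels: per-label sensitivity of the joint consensus
#' set, its false-discovery proportion (fraction of consensus pathways that
#' are truth-null), and — the synthetic analogue of the inter-omic gain —
#' the fraction of split-signal pathways recovered by the joint consensus
#' but by neither single-omic consensus.
#'
#' @param analysis result of [run_interomic_analysis()] on the bundle's data.
#' @param truth the bundle's \code{truth} data.frame.
#' @param class restrict to planted pathways of this drug class (default 1).
#' @return list with \code{sensitivity} (named by label), \code{fdp},
#'   \code{split_joint_only} (fraction), \code{n_split}, and the recovered
#'   sets.
#' @export
evaluate_recovery <- function(analysis, truth, class = 1L) {
  .check(all(truth$pathway_id %in% rownames(analysis$consensus$joint$B)),
         "truth and analysis pathway universes differ")
  joint <- analysis$consensus$joint$consensus
  gene <- analysis$consensus$gene$consensus
  met <- analysis$consensus$metabolite$consensus

  planted <- truth[truth$label != "null" & truth$class == class, ]
  labs <- intersect(c("gene_signal", "metabolite_signal", "split_signal"),
                    planted$label)
  sens <- vapply(labs, function(lab) {
    ids <- planted$pathway_id[planted$label == lab]
    mean(ids %in% joint)
  }, 0)
  null_ids <- truth$pathway_id[truth$label == "null"]
  fdp <- if (length(joint) == 0) 0 else mean(joint %in% null_ids)

  split_ids <- planted$pathway_id[planted$label == "split_signal"]
  joint_only <- split_ids[split_ids %in% joint &
                            !(split_ids %in% gene) & !(split_ids %in% met)]
  list(sensitivity = sens, fdp = fdp,
       split_joint_only = if (length(split_ids) == 0) NA_real_
         else length(joint_only) / length(split_ids),
       n_split = length(split_ids),
       joint_consensus = joint, gene_consensus = gene,
       metabolite_consensus = met, split_recovered_joint_only = joint_only)
}
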