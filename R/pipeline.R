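#' Run the inter-omic consensus analysis in memory
#'
#' Convenience driver over the module functions: correlates both omics
#' matrices with every phenotype, selects significant panels by FDR, runs
#' joint pathway over-representation per drug and builds consensus tables
#' for the joint, gene-only and metabolite-only analyses.
#'
#' @param gene_matrix gene-namespace `omics_matrix`.
#' @param met_matrix metabolite-namespace `omics_matrix`.
#' @param phenotypes named list of phenotype vectors (one per drug).
#' @param db a `pathway_db`.
#' @param fdr_q feature-selection FDR threshold (default 0.60).
#' @param alpha pathway significance level (default 0.05).
#' @param drugs drugs to analyse (default all).
#' @param threshold consensus threshold (default majority of \code{drugs}).
#' @return list with \code{panels} (per drug: gene and metabolite
#'   `feature_panel`s), \code{associations}, \code{enrichments} (per-drug
#'   `enrichment_result`s), \code{consensus} (per mode: `consensus_table`),
#'   \code{panel_sizes} (data.frame fed to [null_model_I()]), and the
#'   parameters used.
#' @export
run_interomic_analysis <- function(gene_matrix, met_matrix, phenotypes, db,
                                   fdr_q = 0.60, alpha = 0.05,
                                   drugs = names(phenotypes),
                                   threshold = majority_threshold(length(drugs))) {
  .check(all(drugs %in% names(phenotypes)), "unknown drug in 'drugs'")
  # currency metabolites (and any feature outside the enrichment background)
  # are removed before analysis
  gene_matrix <- gene_matrix[rownames(gene_matrix) %in% db$measured_genes, ,
                             drop = FALSE]
  met_matrix <- met_matrix[rownames(met_matrix) %in% db$measured_metabolites, ,
                           drop = FALSE]
  associations <- list(); panels <- list(); enrichments <- list()
  for (d in drugs) {
    ag <- correlate(gene_matrix, phenotypes[[d]])
    am <- correlate(met_matrix, phenotypes[[d]])
    pg <- select_significant(ag, fdr_q, drug_id = d)
    pm <- select_significant(am, fdr_q, drug_id = d)
    associations[[d]] <- list(gene = ag, metabolite = am)
    panels[[d]] <- list(gene = pg, metabolite = pm)
    enrichments[[d]] <- enrich_joint(pg, pm, db, alpha)
  }
  universe <- names(db$pathways)
  consensus <- lapply(c(joint = "joint", gene = "gene",
                        metabolite = "metabolite"), function(mode) {
    sets <- lapply(enrichments, significant_pathways, alpha = alpha,
                   mode = mode)
    build_consensus(sets, universe, threshold)
  })
  panel_sizes <- data.frame(
    drug_id = drugs,
    n_genes = vapply(panels, function(p) length(p$gene$selected), 0L),
    n_metabolites = vapply(panels, function(p)
      length(p$metabolite$selected), 0L),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(panels = panels, associations = associations,
       enrichments = enrichments, consensus = consensus,
       panel_sizes = panel_sizes,
       fdr_q = fdr_q, alpha = alpha, threshold = threshold, drugs = drugs)
}

#' Assemble a run configuration for the staged pipeline
#'
#' @param input_dir directory holding the input files in the dialects the
#'   generator writes (see [write_synthetic()]).
#' @param output_dir directory for stage outputs and the manifest.
#' @param fdr_q feature FDR threshold (default 0.60).
#' @param alpha pathway significance level (default 0.05).
#' @param threshold consensus majority threshold (NULL = floor(D/2)+1).
#' @param null_replicates replicates for null model I (default 100).
#' @param permutations permutations for the joint-gain test (default 100).
#' @param seed master seed (default 1).
#' @param currency currency metabolite compound IDs; \code{NULL} reads
#'   \code{currency.txt} from the input directory when present, else uses
#'   [default_currency_metabolites()].
#' @return a `run_config` list.
#' @export
run_config <- function(input_dir, output_dir,
                       fdr_q = 0.60, alpha = 0.05, threshold = NULL,
                       null_replicates = 100L, permutations = 100L,
                       seed = 1L, currency = NULL) {
  .check(fdr_q > 0 && fdr_q < 1, "fdr_q must be in (0, 1)")
  .check(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 fdr_q = fdr_q, alpha = alpha, threshold = threshold,
                 null_replicates = null_replicates,
                 permutations = permutations, seed = seed,
                 currency = currency),
            class = "run_config")
}

#' Run pipeline stages against files on disk
#'
#' Re-entrant staged execution: each stage reads the previous stage's files
#' from the output directory, writes its own outputs, and appends to a JSON
#' manifest recording parameters, seed, package version and MD5 checksums
#' of every file written. Stages: \code{associate} (correlations + panels),
#' \code{enrich} (per-drug joint enrichment TSVs), \code{consensus}
#' (consensus table + exact-n counts), \code{nullmodels} (null models I and
#' II, cumulative FDR, permutation test), \code{cluster} (binary matrix,
#' linkage table, leaf order); \code{all} runs everything in order.
#'
#' @param config a [run_config()].
#' @param stage one of \code{"associate"}, \code{"enrich"},
#'   \code{"consensus"}, \code{"nullmodels"}, \code{"cluster"},
#'   \code{"all"}.
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config,
                         stage = c("all", "associate", "enrich", "consensus",
                                   "nullmodels", "cluster")) {
  stage <- match.arg(stage)
  stages <- if (stage == "all")
    c("associate", "enrich", "consensus", "nullmodels", "cluster") else stage
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  for (s in stages) .run_stage(s, config)
  invisible(.read_manifest(config))
}

.run_stage <- function(stage, config) {
  inputs <- .load_inputs(config)
  out <- function(f) file.path(config$output_dir, f)

  written <- switch(stage,
    associate = {
      files <- character(0)
      for (d in names(inputs$phenotypes)) {
        for (ns in c("gene", "metabolite")) {
          a <- correlate(inputs[[ns]], inputs$phenotypes[[d]])
          p <- select_significant(a, config$fdr_q, drug_id = d)
          f <- out(sprintf("assoc_%s_%s.tsv", d, ns))
          write_association_table(a, p, f)
          files <- c(files, f)
        }
      }
      files
    },
    enrich = {
      files <- character(0)
      for (d in names(inputs$phenotypes)) {
        panels <- lapply(c(gene = "gene", metabolite = "metabolite"),
                         function(ns) {
          f <- out(sprintf("assoc_%s_%s.tsv", d, ns))
          .check(file.exists(f),
                 "missing output of stage 'associate' (%s); run it first", f)
          df <- utils::read.delim(f)
          structure(list(drug_id = d, namespace = ns,
                         selected = df$feature_id[df$selected]),
                    class = "feature_panel")
        })
        res <- enrich_joint(panels$gene, panels$metabolite, inputs$db,
                            config$alpha)
        f <- out(sprintf("enrich_%s.tsv", d))
        utils::write.table(as.data.frame(res), f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        files <- c(files, f)
      }
      files
    },
    consensus = {
      sets <- lapply(names(inputs$phenotypes), function(d) {
        f <- out(sprintf("enrich_%s.tsv", d))
        .check(file.exists(f),
               "missing output of stage 'enrich' (%s); run it first", f)
        df <- utils::read.delim(f)
        df$pathway_id[df$sig_joint]
      })
      names(sets) <- names(inputs$phenotypes)
      thr <- config$threshold %||% majority_threshold(length(sets))
      ct <- build_consensus(sets, names(inputs$db$pathways), thr)
      df <- data.frame(pathway_id = rownames(ct$B), ct$B,
                       n = ct$n_per_pathway,
                       in_consensus = rownames(ct$B) %in% ct$consensus,
                       check.names = FALSE)
      f <- out("consensus.tsv")
      utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
      f
    },
    nullmodels = {
      f_cons <- out("consensus.tsv")
      .check(file.exists(f_cons),
             "missing output of stage 'consensus' (%s); run it first", f_cons)
      cons <- utils::read.delim(f_cons, check.names = FALSE)
      drugs <- names(inputs$phenotypes)
      observed <- vapply(seq_along(drugs), function(n)
        sum(cons$n == n), 0L)
      sizes <- data.frame(
        drug_id = drugs,
        n_genes = vapply(drugs, function(d) {
          df <- utils::read.delim(out(sprintf("assoc_%s_gene.tsv", d)))
          sum(df$selected)
        }, 0),
        n_metabolites = vapply(drugs, function(d) {
          df <- utils::read.delim(out(sprintf("assoc_%s_metabolite.tsv", d)))
          sum(df$selected)
        }, 0))
      nmI <- null_model_I(inputs$db, sizes, R = config$null_replicates,
                          alpha = config$alpha, seed = config$seed)
      S <- vapply(drugs, function(d) {
        df <- utils::read.delim(out(sprintf("enrich_%s.tsv", d)))
        sum(df$sig_joint)
      }, 0)
      nmII <- null_model_II(S, eligible_universe(inputs$db))
      perm <- lapply(drugs, function(d) {
        df <- utils::read.delim(out(sprintf("enrich_%s.tsv", d)))
        permutation_gain_test(df$p_G, df$p_M, alpha = config$alpha,
                              P = config$permutations, seed = config$seed)
      })
      names(perm) <- drugs
      report <- list(
        observed_exact_n = as.list(stats::setNames(observed,
                                                   seq_along(drugs))),
        null_model_I = list(expected_exact_n = as.list(nmI$expected_exact_n),
                            replicates = nmI$replicates, seed = config$seed,
                            cumulative_fdr = cumulative_fdr(
                              observed, nmI$expected_exact_n)),
        null_model_II = list(expected_exact_n = as.list(nmII$expected_exact_n),
                             M = nmII$M,
                             cumulative_fdr = cumulative_fdr(
                               observed, nmII$expected_exact_n)),
        permutation = lapply(perm, function(p)
          p[c("real_count", "exceedance", "P", "empirical_p")]))
      f <- out("null_models.json")
      jsonlite::write_json(report, f, auto_unbox = TRUE, digits = NA,
                           dataframe = "columns")
      f
    },
    cluster = {
      drugs <- names(inputs$phenotypes)
      enr <- lapply(drugs, function(d) {
        f <- out(sprintf("enrich_%s.tsv", d))
        .check(file.exists(f),
               "missing output of stage 'enrich' (%s); run it first", f)
        df <- utils::read.delim(f)
        structure(df, class = c("enrichment_result", "data.frame"))
      })
      names(enr) <- drugs
      B <- build_binary_matrix(enr, alpha = config$alpha)
      f1 <- out("binary_matrix.tsv")
      write_omics_matrix(unclass(B), f1, id_col = "drug_id")
      files <- f1
      if (nrow(B) - length(attr(B, "empty_drugs")) >= 2) {
        hc <- cluster_binary(B, "drugs")
        f2 <- out("linkage_drugs.tsv")
        utils::write.table(hc$linkage, f2, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        f3 <- out("leaf_order_drugs.txt")
        writeLines(hc$labels[hc$order], f3)
        files <- c(files, f2, f3)
      }
      files
    })

  .append_manifest(config, stage, written)
}

.load_inputs <- function(config) {
  ind <- config$input_dir
  fp <- function(f) file.path(ind, f)
  for (f in c("genes.tsv", "metabolites.tsv", "phenotypes.tsv",
              "pathways_gene.gmt", "pathways_metabolite.gmt",
              "measured_genes.txt", "measured_metabolites.txt")) {
    .check(file.exists(fp(f)), "required input %s missing from %s", f, ind)
  }
  id_map <- list()
  if (file.exists(fp("id_map_protein_probe.tsv")))
    id_map$protein_to_probes <- read_id_map(fp("id_map_protein_probe.tsv"))
  if (file.exists(fp("id_map_metabolite_compound.tsv")))
    id_map$metabolite_to_compound <-
      read_id_map(fp("id_map_metabolite_compound.tsv"))
  currency <- config$currency
  if (is.null(currency)) {
    currency <- if (file.exists(fp("currency.txt")))
      read_measured_list(fp("currency.txt")) else default_currency_metabolites()
  }
  db <- build_pathway_db(read_gmt(fp("pathways_gene.gmt"), "gene"),
                         read_gmt(fp("pathways_metabolite.gmt"), "metabolite"),
                         id_map = id_map,
                         measured_genes = read_measured_list(fp("measured_genes.txt")),
                         measured_metabolites =
                           read_measured_list(fp("measured_metabolites.txt")),
                         currency = currency)
  gene <- read_omics_matrix(fp("genes.tsv"), "gene")
  metabolite <- read_omics_matrix(fp("metabolites.tsv"), "metabolite")
  # drop currency metabolites / off-background features before analysis
  gene <- gene[rownames(gene) %in% db$measured_genes, , drop = FALSE]
  metabolite <- metabolite[rownames(metabolite) %in% db$measured_metabolites, ,
                           drop = FALSE]
  list(gene = gene, metabolite = metabolite,
       phenotypes = read_phenotypes(fp("phenotypes.tsv")),
       db = db)
}

.manifest_path <- function(config) file.path(config$output_dir, "manifest.json")

.read_manifest <- function(config) {
  p <- .manifest_path(config)
  if (file.exists(p)) jsonlite::read_json(p) else list()
}

.append_manifest <- function(config, stage, files) {
  manifest <- .read_manifest(config)
  manifest$package_version <-
    as.character(utils::packageVersion("consensusOR"))
  manifest$parameters <- config[c("input_dir", "fdr_q", "alpha", "threshold",
                                  "null_replicates", "permutations", "seed")]
  manifest$stages[[stage]] <- list(
    time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    outputs = lapply(stats::setNames(files, basename(files)), function(f)
      unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, .manifest_path(config), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}
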