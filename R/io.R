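#' Read a GMT pathway membership file
#'
#' Parses the standard tab-separated GMT dialect: one pathway per line,
#' fields \code{id <TAB> description <TAB> member1 <TAB> member2 ...}.
#' Duplicate member IDs within a line are collapsed to one. A namespace tag
#' records whether the members are protein/gene or metabolite identifiers.
#'
#' The parser is strict by design: a line with fewer than three fields (no
#' members) or a pathway ID seen twice aborts with an error naming the line,
#' so that silently empty sets can never enter an enrichment background.
#'
#' @param path path to a GMT file.
#' @param namespace \code{"gene"} or \code{"metabolite"}.
#' @return a list of membership sets, each a list with elements
#'   \code{pathway_id}, \code{name} (the description field), \code{source},
#'   \code{members} (unique character vector), \code{namespace}.
#' @export
read_gmt <- function(path, namespace = c("gene", "metabolite")) {
  namespace <- match.arg(namespace)
  .check(file.exists(path), "GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  seen <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop(sprintf("malformed GMT line %d in %s: expected id, description and >=1 member",
                   i, path), call. = FALSE)
    }
    id <- fields[[1]]
    if (id %in% seen) {
      stop(sprintf("duplicate pathway_id '%s' at GMT line %d in %s", id, i, path),
           call. = FALSE)
    }
    seen <- c(seen, id)
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0L) {
      stop(sprintf("malformed GMT line %d in %s: empty member list", i, path),
           call. = FALSE)
    }
    out[[i]] <- list(pathway_id = id, name = fields[[2]],
                     source = .gmt_source(fields[[2]]),
                     members = members, namespace = namespace)
  }
  out
}

# description fields of the form "desc|source" carry a source database tag;
# plain descriptions get source NA
.gmt_source <- function(desc) {
  parts <- strsplit(desc, "|", fixed = TRUE)[[1]]
  if (length(parts) >= 2L) parts[[length(parts)]] else NA_character_
}

#' Write membership sets to a GMT file
#'
#' @param sets list of membership sets as returned by [read_gmt()], or a
#'   named list of member character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  if (!is.null(names(sets)) && !is.list(sets[[1]])) {
    sets <- lapply(names(sets), function(id)
      list(pathway_id = id, name = id, members = sets[[id]]))
  }
  lines <- vapply(sets, function(s)
    paste(c(s$pathway_id, if (is.null(s$name)) s$pathway_id else s$name,
            s$members), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an ID-mapping table
#'
#' Reads a two-column TSV (\code{source_id}, \code{target_id}), one row per
#' mapping pair, into the many-to-many map used to expand pathway proteins
#' to measured probesets (and metabolite names to compound IDs). Lookups of
#' unknown IDs return an empty vector rather than failing.
#'
#' @param path TSV path with a header row.
#' @return named list mapping each source ID to a character vector of
#'   target IDs.
#' @export
read_id_map <- function(path) {
  .check(file.exists(path), "ID-map file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, colClasses = "character")
  .check(ncol(df) >= 2L, "ID map %s needs columns (source_id, target_id)", path)
  split(df[[2]], df[[1]])
}

#' Write an ID map as a two-column TSV
#' @param map named list of character vectors (source -> targets).
#' @param path output path.
#' @export
write_id_map <- function(map, path) {
  df <- data.frame(
    source_id = rep(names(map), lengths(map)),
    target_id = unlist(map, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a one-ID-per-line measured-feature list
#' @param path text file, one feature ID per line.
#' @return character vector of unique IDs.
#' @export
read_measured_list <- function(path) {
  .check(file.exists(path), "measured-feature list not found: %s", path)
  unique(readLines(path, warn = FALSE))
}

#' Read a feature-by-sample abundance matrix from TSV
#'
#' First column holds feature IDs, the header row holds sample IDs; empty
#' cells and \code{NA} become missing values.
#'
#' @param path TSV path.
#' @param namespace \code{"gene"} or \code{"metabolite"}.
#' @return an `omics_matrix`: a numeric matrix (features x samples) with an
#'   attached namespace attribute.
#' @export
read_omics_matrix <- function(path, namespace = c("gene", "metabolite")) {
  namespace <- match.arg(namespace)
  .check(file.exists(path), "matrix file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE)
  ids <- as.character(df[[1]])
  .check(!anyDuplicated(ids), "duplicate feature IDs in %s", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  .check(!anyDuplicated(colnames(m)), "duplicate sample IDs in %s", path)
  omics_matrix(m, namespace)
}

#' Construct an omics matrix from a numeric matrix
#' @param m numeric matrix, features in rows, samples in columns, both
#'   dimnames set.
#' @param namespace \code{"gene"} or \code{"metabolite"}.
#' @return the matrix with class `omics_matrix` and a namespace attribute.
#' @export
omics_matrix <- function(m, namespace = c("gene", "metabolite")) {
  namespace <- match.arg(namespace)
  .check(!is.null(rownames(m)) && !is.null(colnames(m)),
         "omics matrix needs feature and sample IDs as dimnames")
  structure(m, namespace = namespace,
            class = c("omics_matrix", class(m)))
}

#' @export
`[.omics_matrix` <- function(x, i, j, ..., drop = FALSE) {
  ns <- attr(x, "namespace")
  m <- NextMethod(drop = drop)
  if (is.matrix(m) && !is.null(rownames(m)) && !is.null(colnames(m))) {
    m <- omics_matrix(m, ns)
  }
  m
}

#' Write an omics matrix (or any feature-by-sample table) as TSV
#' @param m matrix with dimnames.
#' @param path output path.
#' @param id_col name for the leading ID column.
#' @export
write_omics_matrix <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-drug phenotype vectors from TSV
#'
#' Drugs in rows (first column = drug ID), samples in columns. Values are
#' replicate-averaged -log(GI50) sensitivities; missing entries allowed.
#'
#' @param path TSV path.
#' @return named list of phenotype vectors (named numeric vectors, names =
#'   sample IDs).
#' @export
read_phenotypes <- function(path) {
  .check(file.exists(path), "phenotype file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE)
  ids <- as.character(df[[1]])
  .check(!anyDuplicated(ids), "duplicate drug IDs in %s", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  stats::setNames(lapply(seq_along(ids), function(i) m[i, ]), ids)
}

#' Write per-drug phenotype vectors as TSV
#' @param phenotypes named list of named numeric vectors.
#' @param path output path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  samples <- names(phenotypes[[1]])
  m <- do.call(rbind, lapply(phenotypes, function(v) v[samples]))
  rownames(m) <- names(phenotypes)
  write_omics_matrix(m, path, id_col = "drug_id")
}
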