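# Readers and writers for the external tabular formats consumed by the
# pipeline. All genomic intervals are 0-based half-open (BED convention);
# TSS is strand-aware (start on '+', end on '-').

#' Construct a matched normal/tumor expression matrix
#'
#' Container for paired expression of `m` genes over `n` patients, with one
#' normal and one tumor measurement per patient. lncRNA and protein-coding
#' gene (PCG) identifiers share a single id space and must be disjoint:
#' a gene carries exactly one class label.
#'
#' @param normal,tumor numeric `m x n` matrices of non-negative expression
#'   values with identical dimnames (gene ids x patient ids).
#' @param gene_class character vector of length `m`, each `"lncRNA"` or
#'   `"PCG"`, named by (or aligned with) the rownames of `normal`.
#' @return An object of class `matched_expr`: a list with elements
#'   `gene_ids`, `gene_class`, `patient_ids`, `normal`, `tumor`.
#' @export
matched_expr <- function(normal, tumor, gene_class) {
  if (!is.matrix(normal) || !is.matrix(tumor))
    stop("normal and tumor must be matrices")
  if (!identical(dim(normal), dim(tumor)))
    stop("normal and tumor must have identical dimensions")
  if (is.null(rownames(normal)) || is.null(colnames(normal)))
    stop("normal must have gene ids as rownames and patient ids as colnames")
  if (!identical(dimnames(normal), dimnames(tumor)))
    stop("normal and tumor must have identical dimnames")
  gene_ids <- rownames(normal)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id: ", gene_ids[duplicated(gene_ids)][1L])
  if (anyDuplicated(colnames(normal)))
    stop("duplicate patient id: ",
         colnames(normal)[duplicated(colnames(normal))][1L])
  if (!is.null(names(gene_class))) gene_class <- gene_class[gene_ids]
  gene_class <- as.character(gene_class)
  if (length(gene_class) != length(gene_ids) || anyNA(gene_class))
    stop("gene_class must be defined for every gene")
  if (!all(gene_class %in% c("lncRNA", "PCG")))
    stop("gene_class values must be 'lncRNA' or 'PCG'")
  if (anyNA(normal) || anyNA(tumor))
    stop("expression values must not be missing")
  if (any(normal < 0) || any(tumor < 0))
    stop("expression values must be non-negative")
  names(gene_class) <- gene_ids
  structure(
    list(gene_ids = gene_ids, gene_class = gene_class,
         patient_ids = colnames(normal), normal = normal, tumor = tumor),
    class = "matched_expr")
}

#' @export
print.matched_expr <- function(x, ...) {
  cat("Matched N/T expression matrix:",
      length(x$gene_ids), "genes (",
      sum(x$gene_class == "lncRNA"), "lncRNA /",
      sum(x$gene_class == "PCG"), "PCG ) x",
      length(x$patient_ids), "patients\n")
  invisible(x)
}

#' Read a matched normal/tumor expression matrix from TSV
#'
#' The expression file has columns `gene_id`, `gene_class`, then one column
#' per sample. `pairing` maps every sample column to a patient and tissue
#' (`N` or `T`); each patient must contribute exactly one normal and one
#' tumor column. Patient order in the result follows first appearance in the
#' pairing table, so permuting the expression columns does not change the
#' result.
#'
#' @param path path to the expression TSV.
#' @param pairing either a path to a TSV with columns
#'   `sample`, `patient`, `tissue`, or a data.frame with those columns.
#' @return A [matched_expr] object.
#' @export
read_matched_expression <- function(path, pairing) {
  expr <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (!all(c("gene_id", "gene_class") %in% names(expr)))
    stop("expression file must have 'gene_id' and 'gene_class' columns")
  if (is.character(pairing) && length(pairing) == 1L)
    pairing <- utils::read.delim(pairing, stringsAsFactors = FALSE)
  if (!all(c("sample", "patient", "tissue") %in% names(pairing)))
    stop("pairing must have 'sample', 'patient', 'tissue' columns")
  if (!all(pairing$tissue %in% c("N", "T")))
    stop("pairing tissue labels must be 'N' or 'T'")

  if (anyDuplicated(expr$gene_id))
    stop("duplicate gene id: ", expr$gene_id[duplicated(expr$gene_id)][1L])

  sample_cols <- setdiff(names(expr), c("gene_id", "gene_class"))
  missing_map <- setdiff(sample_cols, pairing$sample)
  if (length(missing_map))
    stop("sample column(s) not in pairing spec: ",
         paste(missing_map, collapse = ", "))
  pairing <- pairing[pairing$sample %in% sample_cols, , drop = FALSE]

  patient_ids <- unique(pairing$patient)
  for (p in patient_ids) {
    tis <- pairing$tissue[pairing$patient == p]
    if (sum(tis == "N") != 1L || sum(tis == "T") != 1L)
      stop("pairing error: patient ", p,
           " must have exactly one normal and one tumor column")
  }

  vals <- as.matrix(expr[, sample_cols, drop = FALSE])
  if (!is.numeric(vals)) stop("expression values must be numeric")
  if (any(vals < 0))
    stop("negative expression value found; values must be >= 0")
  rownames(vals) <- expr$gene_id

  n_samp <- function(tissue) {
    idx <- match(patient_ids, pairing$patient[pairing$tissue == tissue])
    cols <- pairing$sample[pairing$tissue == tissue][idx]
    m <- vals[, cols, drop = FALSE]
    colnames(m) <- patient_ids
    m
  }
  matched_expr(n_samp("N"), n_samp("T"),
               stats::setNames(expr$gene_class, expr$gene_id))
}

#' Write a matched expression matrix (plus its pairing spec) to TSV
#'
#' Inverse of [read_matched_expression()]; sample columns are named
#' `<patient>_N` and `<patient>_T`.
#'
#' @param x a [matched_expr] object.
#' @param path output path for the expression TSV.
#' @param pairing_path output path for the sample-to-patient pairing TSV.
#' @return Invisibly, `path`.
#' @export
write_matched_expression <- function(x, path, pairing_path) {
  stopifnot(inherits(x, "matched_expr"))
  ncols <- paste0(x$patient_ids, "_N")
  tcols <- paste0(x$patient_ids, "_T")
  out <- data.frame(gene_id = x$gene_ids,
                    gene_class = unname(x$gene_class),
                    stringsAsFactors = FALSE, check.names = FALSE)
  nm <- x$normal; colnames(nm) <- ncols
  tm <- x$tumor;  colnames(tm) <- tcols
  out <- cbind(out, as.data.frame(nm, check.names = FALSE),
               as.data.frame(tm, check.names = FALSE))
  write_results(out, path)
  pairing <- data.frame(
    sample = c(ncols, tcols),
    patient = rep(x$patient_ids, 2L),
    tissue = rep(c("N", "T"), each = length(x$patient_ids)),
    stringsAsFactors = FALSE)
  write_results(pairing, pairing_path)
  invisible(path)
}

#' Read a miRNA-target interaction table
#'
#' A starBase-style TSV with columns `mirna_id`, `target_id`, `target_class`
#' (`lncRNA` or `PCG`). Duplicate rows are collapsed; a target annotated with
#' two different classes is a consistency error.
#'
#' @param path path to the TSV.
#' @return An `interaction_set`: a deduplicated data.frame of edges with
#'   attribute `counts` holding the numbers of distinct miRNAs, lncRNAs and
#'   PCGs.
#' @export
read_interactions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    warning("empty interaction file: ", path)
    df <- data.frame(mirna_id = character(), target_id = character(),
                     target_class = character(), stringsAsFactors = FALSE)
    return(interaction_set(df))
  }
  if (!all(c("mirna_id", "target_id", "target_class") %in% names(df)))
    stop("interaction file must have mirna_id, target_id, target_class")
  interaction_set(df)
}

#' Construct a validated interaction set
#'
#' @param edges data.frame with columns `mirna_id`, `target_id`,
#'   `target_class`.
#' @return The deduplicated edge data.frame with class `interaction_set`.
#' @export
interaction_set <- function(edges) {
  edges <- edges[, c("mirna_id", "target_id", "target_class"), drop = FALSE]
  if (nrow(edges)) {
    if (!all(edges$target_class %in% c("lncRNA", "PCG")))
      stop("target_class must be 'lncRNA' or 'PCG'")
    edges <- unique(edges)
    cls <- tapply(edges$target_class, edges$target_id,
                  function(v) length(unique(v)))
    bad <- names(cls)[cls > 1L]
    if (length(bad))
      stop("target(s) annotated with more than one class: ",
           paste(bad, collapse = ", "))
    edges <- edges[order(edges$mirna_id, edges$target_id), , drop = FALSE]
  }
  rownames(edges) <- NULL
  attr(edges, "counts") <- c(
    mirnas = length(unique(edges$mirna_id)),
    lncrnas = length(unique(edges$target_id[edges$target_class == "lncRNA"])),
    pcgs = length(unique(edges$target_id[edges$target_class == "PCG"])))
  class(edges) <- c("interaction_set", "data.frame")
  edges
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: per line, a set id, a description, then tab-separated member
#' genes. Duplicate members within a set are collapsed; a line without
#' members is a format error.
#'
#' @param path path to the GMT file.
#' @return A `gene_set_collection`: list with `sets` (named list of unique
#'   member vectors) and `labels` (named character of descriptions).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); labels <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("GMT format error at line ", i, ": set has no members")
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members))
      stop("GMT format error at line ", i, ": set has no members")
    sets[[f[1]]] <- members
    labels[f[1]] <- f[2]
  }
  if (anyDuplicated(names(sets))) stop("duplicate set id in GMT")
  gene_set_collection(sets, labels)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (members).
#' @param labels optional named character vector of display labels.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, labels = NULL) {
  if (!length(sets) || is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must be a non-empty uniquely named list")
  if (any(!lengths(sets))) stop("every gene set must be non-empty")
  sets <- lapply(sets, unique)
  structure(list(sets = sets, labels = labels),
            class = "gene_set_collection")
}

#' Write a gene-set collection to a GMT file
#' @param collection a `gene_set_collection`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_gene_sets <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  ids <- names(collection$sets)
  labs <- if (is.null(collection$labels)) ids else collection$labels[ids]
  labs[is.na(labs)] <- ids[is.na(labs)]
  lines <- vapply(seq_along(ids), function(i)
    paste(c(ids[i], labs[i], collection$sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical survival table
#'
#' TSV with columns `patient_id`, `time` (positive days) and `event`
#' (0 = censored, 1 = event).
#'
#' @param path path to the TSV.
#' @return A validated data.frame of class `clinical_table`.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("patient_id", "time", "event") %in% names(df)))
    stop("clinical file must have patient_id, time, event columns")
  clinical_table(df)
}

#' Construct a validated clinical table
#' @param df data.frame with columns `patient_id`, `time`, `event`.
#' @return The data.frame with class `clinical_table`.
#' @export
clinical_table <- function(df) {
  df <- df[, c("patient_id", "time", "event"), drop = FALSE]
  if (anyDuplicated(df$patient_id)) stop("duplicate patient_id")
  if (any(!is.finite(df$time)) || any(df$time <= 0))
    stop("survival time must be positive")
  if (!all(df$event %in% c(0, 1))) stop("event must be 0 or 1")
  rownames(df) <- NULL
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Read SE/TE enhancer regions from a BED-like file
#'
#' Five tab-separated columns without header:
#' `chrom start end class cell_line`, 0-based half-open coordinates, with
#' `class` either `SE` (super-enhancer) or `TE` (typical enhancer).
#'
#' @param path path to the file.
#' @return A validated data.frame of class `enhancer_regions`.
#' @export
read_regions <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end",
                                        "enhancer_class", "cell_line"))
  enhancer_regions(df)
}

#' Construct a validated enhancer-region set
#' @param df data.frame with columns `chrom`, `start`, `end`,
#'   `enhancer_class`, `cell_line` (0-based half-open).
#' @return The data.frame with class `enhancer_regions`.
#' @export
enhancer_regions <- function(df) {
  df <- df[, c("chrom", "start", "end", "enhancer_class", "cell_line"),
           drop = FALSE]
  if (any(df$start < 0) || any(df$start >= df$end))
    stop("coordinate error: regions require 0 <= start < end")
  if (!all(df$enhancer_class %in% c("SE", "TE")))
    stop("enhancer_class must be 'SE' or 'TE'")
  rownames(df) <- NULL
  class(df) <- c("enhancer_regions", "data.frame")
  df
}

#' Read a gene coordinate table
#'
#' TSV with columns `gene_id`, `chrom`, `start`, `end`, `strand`
#' (0-based half-open; strand `+` or `-`). The transcription start site is
#' `start` on `+` and `end` on `-`.
#'
#' @param path path to the TSV.
#' @return A validated data.frame of class `gene_coords` with an added
#'   `tss` column.
#' @export
read_gene_coords <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  gene_coords(df)
}

#' Construct a validated gene coordinate table
#' @param df data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @return The data.frame (plus strand-aware `tss` column) with class
#'   `gene_coords`.
#' @export
gene_coords <- function(df) {
  df <- df[, c("gene_id", "chrom", "start", "end", "strand"), drop = FALSE]
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in coordinates")
  if (any(df$start >= df$end))
    stop("coordinate error: genes require start < end")
  if (!all(df$strand %in% c("+", "-")))
    stop("strand error: strand must be '+' or '-'")
  df$tss <- ifelse(df$strand == "+", df$start, df$end)
  rownames(df) <- NULL
  class(df) <- c("gene_coords", "data.frame")
  df
}

#' Write a result table to TSV
#'
#' Deterministic column order (as in the input), full numeric precision so a
#' round trip through [read_results()] reproduces numeric fields to within
#' 1e-12 and strings exactly.
#'
#' @param x a data.frame (any result table produced by the package).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(x, path) {
  stopifnot(is.data.frame(x))
  x <- as.data.frame(x)
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], function(v) sprintf("%.15g", v))
  tryCatch(
    suppressWarnings(
      utils::write.table(x, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = TRUE)),
    error = function(e) stop("cannot write results to ", path, ": ",
                             conditionMessage(e)))
  invisible(path)
}

#' Read a result table written by [write_results()]
#' @param path path to the TSV.
#' @return A data.frame.
#' @export
read_results <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
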