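#' Read a gene-by-sample FPKM expression matrix
#'
#' Expression matrices are tab-delimited UTF-8 text: a header row of sample
#' IDs, gene symbols in the first column, linear-scale FPKM values in the
#' body. Values must be finite and non-negative; gene symbols and sample IDs
#' must be unique.
#'
#' @param path Path to the tab-delimited file.
#' @return Numeric matrix (genes x samples) with gene symbols as rownames
#'   and sample IDs as colnames.
#' @export
read_expression_matrix <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) {
    stop("expression file must have a header row of sample IDs and a gene column")
  }
  genes <- as.character(raw[[1L]])
  m <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  validate_expression_matrix(m)
  m
}

#' Validate an expression matrix
#'
#' @param m Numeric matrix, genes x samples, FPKM scale.
#' @return The matrix, invisibly, if valid; otherwise an error naming the
#'   offending gene/sample cell.
#' @export
validate_expression_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("expression matrix must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("expression matrix needs gene rownames and sample colnames")
  }
  dup <- rownames(m)[duplicated(rownames(m))]
  if (length(dup)) stop("duplicated gene symbol(s): ", paste(unique(dup), collapse = ", "))
  dup <- colnames(m)[duplicated(colnames(m))]
  if (length(dup)) stop("duplicated sample ID(s): ", paste(unique(dup), collapse = ", "))
  bad <- which(!is.finite(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("invalid FPKM value %s at gene '%s', sample '%s' (must be finite and >= 0)",
                 format(m[bad[1, 1], bad[1, 2]]),
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  invisible(m)
}

#' Write an expression matrix
#'
#' @param m Numeric matrix, genes x samples.
#' @param path Output path (tab-delimited).
#' @export
write_expression_matrix <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PAM50 centroid matrix (Parker layout)
#'
#' Tab-delimited file with gene symbols in the first column and one column
#' per subtype (Basal, HER2E, LumA, LumB, Normal). Values are on the
#' centered log scale of the original centroid files. Gene order is
#' preserved.
#'
#' @param path Path to the tab-delimited centroid file.
#' @param strict If \code{TRUE}, genes outside the canonical 50-gene list are
#'   an error; otherwise they are retained with a warning.
#' @param apply_aliases If \code{TRUE} (default), legacy symbols are kept but
#'   current-HUGO aliases in the file (NUF2, NDC80, ORC6) are translated to
#'   the package's canonical symbols via [pam50_aliases()].
#' @return Numeric matrix (genes x 5 subtypes) with attribute
#'   \code{scale = "centered_log"}.
#' @export
read_centroid_matrix <- function(path, strict = FALSE, apply_aliases = TRUE) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(raw[[1L]])
  m <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  if (apply_aliases) {
    al <- pam50_aliases()
    hit <- rownames(m) %in% names(al)
    rownames(m)[hit] <- al[rownames(m)[hit]]
  }
  missing <- setdiff(pam50_subtypes(), colnames(m))
  if (length(missing)) {
    stop("centroid file is missing subtype column(s): ", paste(missing, collapse = ", "))
  }
  m <- m[, pam50_subtypes(), drop = FALSE]
  if (nrow(m) > 50L) stop("centroid file has more than 50 genes")
  if (anyDuplicated(rownames(m))) stop("duplicated gene symbols in centroid file")
  if (any(!is.finite(m))) stop("centroid file contains missing or non-finite values")
  extra <- setdiff(rownames(m), pam50_genes())
  if (length(extra)) {
    msg <- paste0("gene(s) not in the canonical PAM50 list: ",
                  paste(extra, collapse = ", "))
    if (strict) stop(msg) else warning(msg, "; retained")
  }
  attr(m, "scale") <- "centered_log"
  m
}

#' Write a centroid matrix
#'
#' @param m Numeric matrix, genes x subtypes.
#' @param path Output path.
#' @export
write_centroid_matrix <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-set partition file
#'
#' Two-column tab-delimited file (\code{gene}, \code{cluster}); cluster is an
#' integer 1..K or \code{NA} for genes assigned to no co-expression cluster.
#' Unassigned genes are retained in centroid computations but are not a
#' removable set in the leave-one-gene-cluster-out sweep.
#'
#' @param path Path to the partition file.
#' @return A \code{gene_partition}: named integer vector (NA = unassigned)
#'   with contiguous cluster IDs starting at 1.
#' @export
read_gene_set_partition <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("partition file needs columns gene, cluster")
  gene_partition(stats::setNames(suppressWarnings(as.integer(raw[[2L]])),
                                 as.character(raw[[1L]])))
}

#' Construct and validate a gene-set partition
#'
#' @param assignment Named integer vector mapping gene symbol to cluster ID,
#'   with \code{NA} marking unassigned genes.
#' @return Validated \code{gene_partition} with cluster IDs re-compacted to
#'   1..K in order of first appearance (warning if input IDs were not
#'   contiguous).
#' @export
gene_partition <- function(assignment) {
  if (is.null(names(assignment)) || any(names(assignment) == "")) {
    stop("partition assignment must be a named vector of genes")
  }
  dup <- names(assignment)[duplicated(names(assignment))]
  if (length(dup)) stop("gene(s) listed more than once: ", paste(unique(dup), collapse = ", "))
  genes <- names(assignment)
  assignment <- as.integer(assignment)
  ids <- sort(unique(assignment[!is.na(assignment)]))
  if (length(ids)) {
    if (any(ids < 1L)) stop("cluster IDs must be positive integers")
    if (!identical(ids, seq_along(ids))) {
      warning("cluster IDs not contiguous from 1; re-compacting")
      assignment <- match(assignment, ids)
    }
  }
  structure(stats::setNames(as.integer(assignment), genes),
            class = "gene_partition")
}

#' @export
print.gene_partition <- function(x, ...) {
  k <- n_gene_sets(x)
  cat(sprintf("gene_partition: %d genes, %d cluster(s), %d unassigned\n",
              length(x), k, sum(is.na(x))))
  for (i in seq_len(k)) {
    cat(sprintf("  set %d: %s\n", i, paste(names(x)[which(!is.na(x) & x == i)],
                                           collapse = ", ")))
  }
  if (any(is.na(x))) {
    cat("  unassigned:", paste(names(x)[is.na(x)], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of gene sets in a partition
#'
#' @param partition A \code{gene_partition}.
#' @return Integer count of clusters (unassigned bucket not counted).
#' @export
n_gene_sets <- function(partition) {
  v <- partition[!is.na(partition)]
  if (!length(v)) 0L else max(as.integer(v))
}

#' Write a gene-set partition file
#'
#' @param partition A \code{gene_partition}.
#' @param path Output path.
#' @export
write_gene_set_partition <- function(partition, path) {
  df <- data.frame(gene = names(partition),
                   cluster = as.integer(partition),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

clinical_columns <- function() {
  c("sample_id", "er_status", "pr_status", "her2_status", "nodal_status",
    "endocrine_treated", "age_at_diagnosis", "tumor_size", "histology",
    "os_time", "os_event", "drfi_time", "drfi_event")
}

#' Read a clinical annotation table
#'
#' Tab-delimited with the exact columns: sample_id, er_status, pr_status,
#' her2_status, nodal_status, endocrine_treated, age_at_diagnosis,
#' tumor_size, histology, os_time, os_event, drfi_time, drfi_event.
#' Times are in days; events are 0/1 indicators.
#'
#' @param path Path to the clinical table.
#' @return A validated data.frame, one row per sample.
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  validate_clinical_table(df)
}

#' Validate a clinical table
#'
#' @param df Data.frame with the columns of [read_clinical_table()].
#' @return The data.frame (with \code{endocrine_treated} coerced to logical).
#' @export
validate_clinical_table <- function(df) {
  missing <- setdiff(clinical_columns(), names(df))
  if (length(missing)) stop("clinical table missing column(s): ",
                            paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in clinical table")
  df$endocrine_treated <- as.logical(df$endocrine_treated)
  for (col in c("os_time", "drfi_time")) {
    bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
    if (length(bad)) stop(sprintf("negative %s for sample '%s'", col,
                                  df$sample_id[bad[1]]))
  }
  for (col in c("os_event", "drfi_event")) {
    if (!all(df[[col]] %in% c(0, 1, NA))) stop(col, " must be 0/1")
  }
  df
}

#' Write a clinical table
#'
#' @param df Clinical data.frame.
#' @param path Output path.
#' @export
write_clinical_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
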