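#' Cluster genes by co-expression
#'
#' Surrogate for unsupervised core clustering of the PAM50 genes:
#' average-linkage hierarchical clustering on the distance
#' 1 - Spearman(gene, gene), cut at the configured correlation threshold.
#' Genes ending up as singletons whose best co-expression with any other
#' gene falls below \code{unassign_threshold} are left unassigned, as are
#' genes constant across samples (with a warning). Cluster IDs are
#' relabelled 1..K by decreasing size (ties by first member symbol) so the
#' result is deterministic.
#'
#' @param expr FPKM matrix, genes x samples.
#' @param genes Genes to cluster (default: all rows of \code{expr}).
#' @param cor_threshold Spearman correlation at which the dendrogram is cut
#'   (height 1 - cor_threshold).
#' @param unassign_threshold Minimum best-neighbour |Spearman| for a
#'   singleton to keep a cluster of its own.
#' @return A \code{gene_partition} over \code{genes}.
#' @export
cluster_genes <- function(expr, genes = rownames(expr),
                          cor_threshold = 0.5, unassign_threshold = 0.3) {
  genes <- intersect(genes, rownames(expr))
  if (ncol(expr) < 20L) {
    warning("fewer than 20 samples; co-expression estimates will be unstable")
  }
  m <- t(log2_fpkm(expr[genes, , drop = FALSE]))
  const <- apply(m, 2, function(v) stats::sd(v) == 0)
  if (any(const)) {
    warning("constant gene(s) left unassigned: ",
            paste(genes[const], collapse = ", "))
  }
  use <- genes[!const]
  assignment <- stats::setNames(rep(NA_integer_, length(genes)), genes)
  if (length(use) >= 2L) {
    rho <- stats::cor(m[, use, drop = FALSE], method = "spearman")
    hc <- stats::hclust(stats::as.dist(1 - rho), method = "average")
    cl <- stats::cutree(hc, h = 1 - cor_threshold)
    diag(rho) <- NA
    best <- apply(abs(rho), 1, max, na.rm = TRUE)
    sizes <- table(cl)
    singleton <- names(cl)[cl %in% as.integer(names(sizes)[sizes == 1L])]
    drop <- singleton[best[singleton] < unassign_threshold]
    cl[drop] <- NA
    # relabel by decreasing size, ties by first member symbol
    keep <- sort(unique(cl[!is.na(cl)]))
    if (length(keep)) {
      first_member <- vapply(keep, function(k) sort(names(cl)[which(cl == k)])[1L],
                             character(1))
      ord <- keep[order(-as.integer(table(factor(cl, levels = keep))),
                        first_member)]
      assignment[names(cl)] <- match(cl, ord)
    }
  }
  gene_partition(assignment)
}

#' Manually split one cluster of a partition
#'
#' Replaces a cluster by explicitly listed sub-clusters (for example
#' separating the 17q12 amplicon pair ERBB2/GRB7 from FGFR4). The listed
#' gene sets must exactly cover the cluster; IDs are re-compacted.
#'
#' @param partition A \code{gene_partition}.
#' @param cluster_id Cluster to split.
#' @param into List of gene-symbol vectors, disjoint, covering the cluster.
#' @return New \code{gene_partition} with the split applied.
#' @export
split_cluster <- function(partition, cluster_id, into) {
  members <- names(partition)[which(!is.na(partition) & partition == cluster_id)]
  if (!length(members)) stop("no such cluster: ", cluster_id)
  listed <- unlist(into, use.names = FALSE)
  if (anyDuplicated(listed) || !setequal(listed, members)) {
    stop("split gene lists must exactly cover cluster ", cluster_id)
  }
  if (length(into) == 1L) return(partition)  # trivial split is the identity
  k <- n_gene_sets(partition)
  out <- as.integer(partition)
  names(out) <- names(partition)
  for (j in seq_along(into)) {
    out[into[[j]]] <- k + j
  }
  gene_partition(stats::setNames(match(out, sort(unique(out[!is.na(out)]))),
                                 names(out)))
}

#' Gene-set scores
#'
#' Per sample and gene set, the mean log2(FPKM + 0.1) over member genes —
#' no gene centering.
#'
#' @param expr FPKM matrix, genes x samples.
#' @param partition A \code{gene_partition}.
#' @return Matrix, samples x gene sets.
#' @export
gene_set_scores <- function(expr, partition) {
  k <- n_gene_sets(partition)
  L <- log2_fpkm(expr)
  out <- matrix(NA_real_, nrow = ncol(expr), ncol = k,
                dimnames = list(colnames(expr), paste0("set", seq_len(k))))
  for (i in seq_len(k)) {
    members <- intersect(names(partition)[which(!is.na(partition) & partition == i)],
                         rownames(expr))
    if (!length(members)) stop("gene set ", i, " has no measured genes")
    out[, i] <- colMeans(L[members, , drop = FALSE])
  }
  out
}

#' Rank-based metagene scores
#'
#' For each member gene, samples are ranked ascending by FPKM (mid-ranks
#' for ties) and scaled to [0, 1] as (rank - 1) / (n - 1); the metagene
#' score is the mean scaled rank over member genes. Rank-based, so invariant
#' to any strictly increasing per-gene transform of FPKM.
#'
#' @param expr FPKM matrix, genes x samples (needs >= 2 samples).
#' @param metagenes Named list of gene-symbol vectors.
#' @return Matrix, samples x metagenes, values in [0, 1].
#' @export
metagene_rank_scores <- function(expr, metagenes) {
  n <- ncol(expr)
  if (n < 2L) stop("metagene rank scores need at least 2 samples")
  if (is.null(names(metagenes))) names(metagenes) <- paste0("metagene", seq_along(metagenes))
  out <- matrix(NA_real_, nrow = n, ncol = length(metagenes),
                dimnames = list(colnames(expr), names(metagenes)))
  for (j in seq_along(metagenes)) {
    present <- intersect(metagenes[[j]], rownames(expr))
    if (!length(present)) stop("metagene '", names(metagenes)[j], "' has no measured genes")
    if (length(present) < length(metagenes[[j]])) {
      warning("metagene '", names(metagenes)[j], "': dropping unmeasured gene(s) ",
              paste(setdiff(metagenes[[j]], present), collapse = ", "))
    }
    scaled <- apply(expr[present, , drop = FALSE], 1,
                    function(v) (rank(v) - 1) / (n - 1))
    out[, j] <- rowMeans(scaled)
  }
  out
}
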