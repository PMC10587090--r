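#' The shipped PAM50 gene-set partition
#'
#' Partition of the 50 PAM50 genes into seven co-expression clusters plus an
#' unassigned bucket, the structure the perturbation sweep removes one set
#' at a time:
#' \describe{
#'   \item{set 1 (21 genes)}{proliferation / mitotic checkpoint (MKI67,
#'     CENPF, CCNE1, TYMS, KIF2C, ...)}
#'   \item{set 2 (9 genes)}{steroid response / luminal differentiation
#'     (ESR1, FOXA1, PGR, BCL2, SLC39A6, MAPT, NAT1, MLPH, CXXC5)}
#'   \item{set 3 (8 genes)}{basal keratins and associated genes (KRT5,
#'     KRT14, KRT17, CDH3, MIA, SFRP1, EGFR, FOXC1)}
#'   \item{set 4}{ERBB2/GRB7, the 17q12 amplicon pair}
#'   \item{set 5}{ACTR3B, PHGDH}
#'   \item{set 6}{GPR160, TMEM45B}
#'   \item{set 7}{FGFR4 (singleton)}
#'   \item{unassigned}{MYC, MMP11, BAG1, MDM2, BLVRA}
#' }
#' Sets 4, 6, 7 and the unassigned bucket are fixed by construction; the
#' remaining membership completes the clusters by canonical gene biology
#' (see the methods vignette for the provenance of each set).
#'
#' @return A \code{gene_partition} over all 50 PAM50 genes.
#' @export
pam50_fixture_partition <- function() {
  sets <- list(
    `1` = c("ANLN", "BIRC5", "CCNB1", "CCNE1", "CDC20", "CDC6", "CDCA1",
            "CENPF", "CEP55", "EXO1", "KIF2C", "KNTC2", "MELK", "MKI67",
            "MYBL2", "ORC6L", "PTTG1", "RRM2", "TYMS", "UBE2C", "UBE2T"),
    `2` = c("BCL2", "CXXC5", "ESR1", "FOXA1", "MAPT", "MLPH", "NAT1",
            "PGR", "SLC39A6"),
    `3` = c("CDH3", "EGFR", "FOXC1", "KRT14", "KRT17", "KRT5", "MIA",
            "SFRP1"),
    `4` = c("ERBB2", "GRB7"),
    `5` = c("ACTR3B", "PHGDH"),
    `6` = c("GPR160", "TMEM45B"),
    `7` = "FGFR4"
  )
  unassigned <- c("MYC", "MMP11", "BAG1", "MDM2", "BLVRA")
  assignment <- stats::setNames(rep(NA_integer_, 50L), pam50_genes())
  for (k in seq_along(sets)) assignment[sets[[k]]] <- k
  stopifnot(identical(sort(names(assignment)[is.na(assignment)]),
                      sort(unassigned)))
  gene_partition(assignment)
}

# Cluster-level prototype values (centered log2 scale) behind the synthetic
# centroids: rows follow the fixture partition's sets 1-7 plus the
# unassigned bucket, columns the five subtypes. Chosen so the inter-centroid
# correlation structure matches the canonical PAM50 pattern: Basal closest
# to HER2E/Normal, HER2E to LumB/Basal, LumA to LumB/Normal, LumB to
# LumA/HER2E, Normal to LumA/Basal.
centroid_cluster_prototypes <- function() {
  m <- rbind(
    prolif  = c(Basal = 0.55, HER2E = 0.45, LumA = -0.95, LumB = 0.75, Normal = -0.80),
    steroid = c(-1.30, -0.70, 0.95, 0.75, 0.30),
    basal   = c(1.30, -0.10, -0.55, -0.65, 0.45),
    erbb2   = c(-0.30, 1.60, -0.25, 0.10, -0.25),
    set5    = c(0.95, 0.15, -0.45, 0.05, -0.35),
    set6    = c(-0.90, 0.25, 0.50, 0.55, -0.20),
    fgfr4   = c(-0.20, 1.10, -0.30, 0.05, -0.15),
    unassigned = c(0.15, 0.25, -0.10, 0.20, -0.25)
  )
  colnames(m) <- pam50_subtypes()
  m
}

#' Synthetic Parker-style PAM50 centroid matrix
#'
#' Deterministically constructed 50-gene x 5-subtype centroid matrix on the
#' centered log2 scale. It is a synthetic stand-in for the original PAM50
#' centroid file (which is distributed with the original publication, not
#' here): per-gene values are a cluster-level subtype prototype (see
#' [pam50_fixture_partition()]) plus small fixed gene- and subtype-specific
#' offsets that break exact ties. The construction reproduces the canonical
#' qualitative inter-centroid correlation pattern of PAM50.
#'
#' @return Numeric matrix (50 genes x 5 subtypes), attribute
#'   \code{scale = "centered_log"}.
#' @export
synthetic_pam50_centroids <- function() {
  part <- pam50_fixture_partition()
  proto <- centroid_cluster_prototypes()
  genes <- names(part)
  cluster_row <- ifelse(is.na(part), 8L, as.integer(part))
  m <- proto[cluster_row, , drop = FALSE]
  rownames(m) <- genes

  # deterministic within-cluster gene offsets (shared across subtypes) and a
  # tiny subtype-specific jitter so no two genes or correlations tie exactly
  for (k in sort(unique(cluster_row))) {
    idx <- which(cluster_row == k)
    sz <- length(idx)
    gene_off <- if (sz > 1) 0.15 * (seq_len(sz) - (sz + 1) / 2) / ((sz - 1) / 2) else 0
    m[idx, ] <- m[idx, , drop = FALSE] + gene_off
  }
  i <- rep(seq_along(genes), times = 5L)
  s <- rep(seq_len(5L), each = length(genes))
  # the pi-scaled term keeps every within-column pair of values distinct:
  # cluster means and offsets are rational, so no two genes can collide
  jitter <- ((7L * i + 13L * s) %% 11L - 5L) / 250 + i * pi * 1e-4
  m <- m + matrix(jitter, nrow = length(genes), ncol = 5L)
  attr(m, "scale") <- "centered_log"
  m
}

#' Pearson inter-correlation of subtype centroids
#'
#' Correlation between the five centroid columns over their shared genes;
#' the off-diagonal structure explains which second-best subtypes co-occur
#' with each called subtype.
#'
#' @param centroids Centroid matrix, genes x subtypes.
#' @return Symmetric 5 x 5 Pearson correlation matrix with unit diagonal.
#' @export
centroid_intercorrelation <- function(centroids) {
  stats::cor(centroids, method = "pearson")
}

#' Mean centroid value per gene set
#'
#' @param centroids Centroid matrix, genes x subtypes.
#' @param partition A \code{gene_partition}; genes absent from the centroid
#'   matrix are ignored.
#' @return Matrix, subtypes x gene sets, of arithmetic means of centroid
#'   entries over member genes.
#' @export
centroid_geneset_means <- function(centroids, partition) {
  k <- n_gene_sets(partition)
  out <- matrix(NA_real_, nrow = ncol(centroids), ncol = k,
                dimnames = list(colnames(centroids), paste0("set", seq_len(k))))
  for (i in seq_len(k)) {
    members <- intersect(names(partition)[which(!is.na(partition) & partition == i)],
                         rownames(centroids))
    if (length(members)) {
      out[, i] <- colMeans(centroids[members, , drop = FALSE])
    }
  }
  out
}
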