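#' Build refined FPKM-scale centroids from perturbation-stable tumors
#'
#' K0 tumors — samples that never switch subtype under any single gene-set
#' exclusion — are taken as core representatives of their called subtype
#' within a clinical subgroup. Per subtype, the refined centroid is the
#' arithmetic mean FPKM per gene over the contributing K0 tumors (no
#' offset, no log transform, no centering). Subtypes with fewer than
#' \code{min_k0_per_subtype} contributing tumors are dropped with a warning.
#'
#' @param expr FPKM matrix, genes x samples.
#' @param cls The \code{ensemble_classification} providing \code{pam50_nc}.
#' @param k0_flags Data.frame \code{sample_id}, \code{k0} from
#'   [perturbation_sweep()].
#' @param subgroup_filter Optional: restrict contributing samples to one
#'   clinical subgroup; needs \code{grouping}.
#' @param grouping Clinical subgroup per sample of \code{cls} (required when
#'   \code{subgroup_filter} is given).
#' @param min_k0_per_subtype Minimum contributing tumors per subtype
#'   (default 5; set to 1 for a literal single-tumor centroid).
#' @return Matrix genes x available subtypes, attribute
#'   \code{scale = "fpkm"} and \code{n_contributing} (named counts).
#' @export
build_k0_centroids <- function(expr, cls, k0_flags, subgroup_filter = NULL,
                               grouping = NULL, min_k0_per_subtype = 5L) {
  keep <- cls$sample_id[match(k0_flags$sample_id[k0_flags$k0], cls$sample_id)]
  if (!is.null(subgroup_filter)) {
    if (is.null(grouping)) stop("grouping required with subgroup_filter")
    in_grp <- cls$sample_id[grouping == subgroup_filter]
    keep <- intersect(keep, in_grp)
  }
  keep <- intersect(keep, colnames(expr))
  if (!length(keep)) stop("no K0 samples available for centroid construction")
  calls <- cls$pam50_nc[match(keep, cls$sample_id)]
  counts <- table(calls)
  use <- names(counts)[counts >= min_k0_per_subtype]
  dropped <- setdiff(names(counts), use)
  if (length(dropped)) {
    warning("subtype(s) below min_k0_per_subtype dropped: ",
            paste(sprintf("%s (n=%d)", dropped, as.integer(counts[dropped])),
                  collapse = ", "))
  }
  if (!length(use)) stop("no subtype has enough K0 samples")
  out <- vapply(use, function(st) {
    rowMeans(expr[, keep[calls == st], drop = FALSE])
  }, numeric(nrow(expr)))
  out <- matrix(out, nrow = nrow(expr),
                dimnames = list(rownames(expr), use))
  attr(out, "scale") <- "fpkm"
  attr(out, "n_contributing") <- stats::setNames(as.integer(counts[use]), use)
  out
}

#' Single-sample classification against K0 centroids
#'
#' Correlates each tumor's raw FPKM profile (no offset, no log2 transform,
#' no gene centering) with every available K0 centroid by Spearman
#' correlation and calls the argmax. No minimum correlation cut-off; exact
#' ties break to the first subtype in alphabetical order. Being rank-based,
#' calls are invariant to any strictly increasing transform of a sample's
#' profile.
#'
#' @param expr FPKM matrix, genes x samples.
#' @param k0_centroids Centroid matrix from [build_k0_centroids()].
#' @return Data.frame: sample_id, pam50_k0, degenerate flag, and cor_* per
#'   available subtype. Constant profiles get \code{NA} calls with a
#'   warning.
#' @export
classify_k0 <- function(expr, k0_centroids) {
  shared <- intersect(rownames(expr), rownames(k0_centroids))
  if (length(shared) < 3L) stop("fewer than 3 genes shared with K0 centroids")
  e <- expr[shared, , drop = FALSE]
  rho <- suppressWarnings(stats::cor(e, k0_centroids[shared, , drop = FALSE],
                                     method = "spearman"))
  degenerate <- !stats::complete.cases(rho)
  if (any(degenerate)) {
    warning("degenerate constant profile(s): ",
            paste(colnames(expr)[degenerate], collapse = ", "))
  }
  call <- colnames(k0_centroids)[max.col(replace(rho, is.na(rho), -Inf),
                                         ties.method = "first")]
  call[degenerate] <- NA_character_
  out <- data.frame(sample_id = colnames(expr), pam50_k0 = call,
                    degenerate = degenerate, stringsAsFactors = FALSE)
  colnames(rho) <- paste0("cor_", colnames(k0_centroids))
  cbind(out, as.data.frame(rho, row.names = NULL))
}

#' Transition table between ensemble and K0 calls
#'
#' Cross-tabulates the original \code{pam50_nc} subtype against the refined
#' \code{pam50_k0} subtype over the shared sample universe; the diagonal
#' counts unchanged tumors.
#'
#' @param cls The \code{ensemble_classification}.
#' @param k0_calls Result of [classify_k0()].
#' @return 5 x 5 contingency table (levels: all five subtypes).
#' @export
transition_table <- function(cls, k0_calls) {
  m <- merge(cls[, c("sample_id", "pam50_nc")],
             k0_calls[, c("sample_id", "pam50_k0")], by = "sample_id")
  lv <- pam50_subtypes()
  table(pam50_nc = factor(m$pam50_nc, levels = lv),
        pam50_k0 = factor(m$pam50_k0, levels = lv))
}
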