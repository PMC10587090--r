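#' Core gene universe of a partition
#'
#' The union of genes in the clustered sets: the background centroid gene
#' content of the leave-one-gene-cluster-out sweep. Unassigned genes are
#' excluded.
#'
#' @param partition A \code{gene_partition}.
#' @return Character vector of gene symbols.
#' @export
core_gene_universe <- function(partition) {
  names(partition)[!is.na(partition)]
}

#' Restrict classification inputs to a reduced gene set
#'
#' Removes one gene set from the centroid matrix, the reference-set
#' centering matrix and the expression matrix, leaving the three structures
#' restricted to the identical, order-aligned remaining gene list within the
#' core gene universe. \code{gene_set_id = 0} (or \code{NULL}) is the
#' identity perturbation: nothing is removed (test hook).
#'
#' @param centroids Centroid matrix, genes x subtypes.
#' @param refsets A \code{reference_sets} object.
#' @param expr FPKM matrix, genes x samples.
#' @param partition A \code{gene_partition} defining the sets and the core
#'   universe.
#' @param gene_set_id Integer ID of the set to remove, or 0/NULL for none.
#' @return List with reduced \code{centroids}, \code{refsets}, \code{expr}.
#' @export
exclude_gene_set <- function(centroids, refsets, expr, partition, gene_set_id) {
  k <- n_gene_sets(partition)
  id <- if (is.null(gene_set_id)) 0L else as.integer(gene_set_id)
  if (id < 0L || id > k) stop("no such gene set: ", gene_set_id)
  background <- core_gene_universe(partition)
  removed <- if (id == 0L) character() else
    names(partition)[which(!is.na(partition) & partition == id)]
  keep <- Reduce(intersect, list(setdiff(background, removed),
                                 rownames(centroids),
                                 rownames(refsets$centering),
                                 rownames(expr)))
  if (length(keep) < 3L) {
    stop("fewer than 3 genes remain after excluding gene set ", id)
  }
  red <- refsets
  red$centering <- refsets$centering[keep, , drop = FALSE]
  list(centroids = centroids[keep, , drop = FALSE],
       refsets = red,
       expr = expr[keep, , drop = FALSE])
}

#' Reclassify after excluding one gene set
#'
#' Runs the identical ensemble machinery of [classify_ensemble()] on the
#' reduced matrices produced by [exclude_gene_set()]; no minimum correlation
#' cut-off applies.
#'
#' @inheritParams exclude_gene_set
#' @return An \code{ensemble_classification} of the perturbed runs (its
#'   \code{pam50_nc} column is the perturbed call).
#' @export
perturb_classify <- function(expr, refsets, centroids, partition, gene_set_id) {
  red <- exclude_gene_set(centroids, refsets, expr, partition, gene_set_id)
  classify_ensemble(red$expr, red$refsets, red$centroids)
}

#' Subtype switch rule
#'
#' A sample switches subtype when its original call is observed in at most
#' half of the perturbed reclassifications: votes for \code{pam50_nc}
#' \eqn{\le} floor(n_sets / 2) (with 100 runs, 50 or fewer).
#'
#' @param vote_counts Named vote counts per subtype, summing to
#'   \code{n_sets}.
#' @param pam50_nc The unperturbed call.
#' @param n_sets Number of ensemble runs.
#' @return Logical.
#' @export
call_switch <- function(vote_counts, pam50_nc, n_sets) {
  if (sum(vote_counts) != n_sets) stop("vote counts must sum to n_sets")
  if (!pam50_nc %in% names(vote_counts)) {
    stop("no vote count for subtype '", pam50_nc, "'")
  }
  unname(vote_counts[pam50_nc] <= n_sets %/% 2L)
}

#' Leave-one-gene-cluster-out perturbation sweep
#'
#' For every gene set of the partition, excludes the set, reclassifies the
#' whole cohort with the full reference-set ensemble, and records per sample
#' the perturbed majority call, its vote counts, the switch flag, the mean
#' correlation change and whether a switched call lands on the second-best
#' subtype. Samples whose original call never switches in any perturbation
#' are flagged K0.
#'
#' @param expr FPKM matrix, genes x samples (core-universe scale; the
#'   unperturbed classification \code{cls} must come from the same
#'   background gene content).
#' @param refsets A \code{reference_sets} object.
#' @param centroids Centroid matrix.
#' @param partition A \code{gene_partition}.
#' @param cls The unperturbed \code{ensemble_classification}.
#' @param gene_set_ids Sets to sweep (default: all).
#' @return List with \code{records} (data.frame, one row per sample x gene
#'   set: pam50_perturb, votes_*, switch, corr_delta, matches_2nd) and
#'   \code{k0} (data.frame sample_id, k0).
#' @export
perturbation_sweep <- function(expr, refsets, centroids, partition, cls,
                               gene_set_ids = seq_len(n_gene_sets(partition))) {
  stopifnot(identical(cls$sample_id, colnames(expr)))
  subtypes <- colnames(centroids)
  nc_cor <- as.matrix(cls[, paste0("mean_cor_", subtypes)])
  nc_idx <- match(cls$pam50_nc, subtypes)
  cor_to_nc <- nc_cor[cbind(seq_len(nrow(cls)), nc_idx)]

  records <- vector("list", length(gene_set_ids))
  for (g in seq_along(gene_set_ids)) {
    id <- gene_set_ids[g]
    pcls <- perturb_classify(expr, refsets, centroids, partition, id)
    p_cor <- as.matrix(pcls[, paste0("mean_cor_", subtypes)])
    p_idx <- match(pcls$pam50_nc, subtypes)
    cor_to_perturb <- p_cor[cbind(seq_len(nrow(pcls)), p_idx)]
    vt <- as.matrix(pcls[, paste0("votes_", subtypes)])
    nc_votes <- vt[cbind(seq_len(nrow(pcls)), nc_idx)]
    switch <- nc_votes <= refsets$n_sets %/% 2L
    matches_2nd <- ifelse(switch & !is.na(cls$pam50_nc_2nd),
                          pcls$pam50_nc == cls$pam50_nc_2nd, NA)
    rec <- data.frame(sample_id = cls$sample_id, gene_set_id = id,
                      pam50_perturb = pcls$pam50_nc,
                      switch = switch,
                      corr_delta = cor_to_perturb - cor_to_nc,
                      matches_2nd = matches_2nd,
                      stringsAsFactors = FALSE)
    records[[g]] <- cbind(rec, as.data.frame(vt))
  }
  records <- do.call(rbind, records)
  rownames(records) <- NULL
  k0 <- data.frame(sample_id = cls$sample_id,
                   k0 = !cls$sample_id %in% records$sample_id[records$switch],
                   stringsAsFactors = FALSE)
  list(records = records, k0 = k0)
}

#' Summaries of the perturbation sweep
#'
#' Aggregates switch records into (1) switch proportions per called subtype,
#' clinical subgroup and gene set, (2) the distribution of perturbed
#' subtypes among switchers, and (3) the proportion of switchers whose
#' perturbed subtype equals their second-best subtype. Denominators are
#' reported alongside; empty strata yield \code{NA} proportions with n = 0.
#'
#' @param records The \code{records} of [perturbation_sweep()].
#' @param cls The unperturbed \code{ensemble_classification}.
#' @param grouping Optional clinical subgroup per sample of \code{cls}.
#' @return List with data.frames \code{switch_proportions},
#'   \code{perturb_distribution} and \code{matches_2nd}.
#' @export
switch_summary <- function(records, cls, grouping = NULL) {
  if (is.null(grouping)) grouping <- rep("all", nrow(cls))
  info <- data.frame(sample_id = cls$sample_id, pam50_nc = cls$pam50_nc,
                     subgroup = grouping, stringsAsFactors = FALSE)
  rec <- merge(records, info, by = "sample_id", sort = FALSE)

  agg <- function(df) {
    data.frame(n = nrow(df),
               n_switch = sum(df$switch),
               prop_switch = if (nrow(df)) mean(df$switch) else NA_real_)
  }
  key <- interaction(rec$pam50_nc, rec$subgroup, rec$gene_set_id, drop = TRUE)
  parts <- split(rec, key)
  sp <- do.call(rbind, lapply(parts, agg))
  meta <- do.call(rbind, strsplit(names(parts), ".", fixed = TRUE))
  switch_proportions <- data.frame(pam50_nc = meta[, 1], subgroup = meta[, 2],
                                   gene_set_id = as.integer(meta[, 3]),
                                   sp, row.names = NULL,
                                   stringsAsFactors = FALSE)

  sw <- rec[rec$switch, , drop = FALSE]
  perturb_distribution <- as.data.frame(
    table(gene_set_id = sw$gene_set_id, pam50_nc = sw$pam50_nc,
          pam50_perturb = sw$pam50_perturb),
    stringsAsFactors = FALSE)

  m2 <- sw[!is.na(sw$matches_2nd), , drop = FALSE]
  km <- interaction(m2$pam50_nc, m2$subgroup, m2$gene_set_id, drop = TRUE)
  mparts <- split(m2, km)
  mm <- do.call(rbind, lapply(mparts, function(df) {
    data.frame(n_switched = nrow(df), prop_matches_2nd = mean(df$matches_2nd))
  }))
  mmeta <- do.call(rbind, strsplit(names(mparts), ".", fixed = TRUE))
  matches_2nd <- if (length(mparts)) {
    data.frame(pam50_nc = mmeta[, 1], subgroup = mmeta[, 2],
               gene_set_id = as.integer(mmeta[, 3]), mm, row.names = NULL,
               stringsAsFactors = FALSE)
  } else {
    data.frame(pam50_nc = character(), subgroup = character(),
               gene_set_id = integer(), n_switched = integer(),
               prop_matches_2nd = numeric())
  }
  list(switch_proportions = switch_proportions,
       perturb_distribution = perturb_distribution,
       matches_2nd = matches_2nd)
}
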