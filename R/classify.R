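log2_fpkm <- function(x, offset = 0.1) log2(x + offset)

#' Build reference sets for gene centering
#'
#' Draws \code{n_sets} balanced subsamples of the cohort (without
#' replacement within each set, the configured number of samples per
#' subtype) and computes each set's per-gene centering vector as the median
#' of log2(FPKM + 0.1) over the set's samples. The provisional labels used
#' for balancing can come from any source (generating truth in simulations,
#' or a first-pass classification on real data).
#'
#' @param expr FPKM matrix, genes x samples.
#' @param labels Provisional subtype label per sample (named by sample ID or
#'   in column order of \code{expr}).
#' @param composition Named counts per subtype drawn into every set
#'   (default: 5 of each subtype present in \code{labels}).
#' @param n_sets Number of reference sets (default 100).
#' @param seed Integer seed for the draws.
#' @param statistic Centering statistic, \code{"median"} (default) or
#'   \code{"mean"}.
#' @return List of class \code{reference_sets}: \code{sets} (list of sample
#'   ID vectors), \code{centering} (genes x n_sets matrix), \code{n_sets},
#'   \code{statistic}.
#' @export
build_reference_sets <- function(expr, labels, composition = NULL,
                                 n_sets = 100L, seed = 1L,
                                 statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  if (is.null(names(labels))) names(labels) <- colnames(expr)
  labels <- labels[colnames(expr)]
  if (is.null(composition)) {
    composition <- stats::setNames(rep(5L, length(unique(labels))),
                                   sort(unique(labels)))
  }
  for (st in names(composition)) {
    have <- sum(labels == st, na.rm = TRUE)
    if (have < composition[[st]]) {
      stop(sprintf("cannot draw %d '%s' samples for reference sets: only %d labeled",
                   composition[[st]], st, have))
    }
  }
  set.seed(seed)
  L <- log2_fpkm(expr)
  stat_fun <- if (statistic == "median") stats::median else mean
  sets <- vector("list", n_sets)
  centering <- matrix(NA_real_, nrow = nrow(expr), ncol = n_sets,
                      dimnames = list(rownames(expr), NULL))
  for (i in seq_len(n_sets)) {
    ids <- unlist(lapply(names(composition), function(st) {
      pool <- colnames(expr)[which(labels == st)]
      if (length(pool) == 1L) pool else sample(pool, composition[[st]])
    }), use.names = FALSE)
    sets[[i]] <- ids
    centering[, i] <- apply(L[, ids, drop = FALSE], 1, stat_fun)
  }
  structure(list(sets = sets, centering = centering,
                 n_sets = as.integer(n_sets), statistic = statistic),
            class = "reference_sets")
}

#' Classify one sample against the PAM50 centroids
#'
#' Centers the sample's log2(FPKM + 0.1) profile with the supplied per-gene
#' centering vector, computes the Spearman correlation to each centroid
#' column over the shared genes, and returns all correlations together with
#' the nearest (highest-correlation) subtype. There is no minimum
#' correlation cut-off: the argmax is returned even if every correlation is
#' negative. Exact correlation ties break to the first subtype in the fixed
#' alphabetical order.
#'
#' @param sample_fpkm Named numeric vector of FPKM values for one sample.
#' @param centering Named numeric per-gene centering values (log2 scale).
#' @param centroids Centroid matrix, genes x subtypes.
#' @return List with \code{correlations} (named over subtypes) and
#'   \code{call}; for a constant centered profile, \code{call} is \code{NA}
#'   and \code{degenerate} is \code{TRUE} (with a warning).
#' @export
classify_single <- function(sample_fpkm, centering, centroids) {
  shared <- Reduce(intersect, list(names(sample_fpkm), names(centering),
                                   rownames(centroids)))
  if (length(shared) < 3L) {
    stop("fewer than 3 genes shared among sample, centering and centroids")
  }
  centered <- log2_fpkm(sample_fpkm[shared]) - centering[shared]
  if (stats::sd(centered) == 0) {
    warning("degenerate profile: centered expression is constant; sample excluded")
    return(list(correlations = stats::setNames(rep(NA_real_, ncol(centroids)),
                                               colnames(centroids)),
                call = NA_character_, degenerate = TRUE))
  }
  rho <- drop(stats::cor(centered, centroids[shared, , drop = FALSE],
                         method = "spearman"))
  list(correlations = rho, call = colnames(centroids)[which.max(rho)],
       degenerate = FALSE)
}

# per-sample summary of an n_sets x 5 vote/correlation ensemble; factored out
# so the vote and second-best arithmetic is testable in isolation
summarize_ensemble <- function(vote_counts, mean_cor, n_sets) {
  subtypes <- names(mean_cor)
  top <- max(vote_counts)
  tied <- subtypes[vote_counts == top]
  if (length(tied) > 1L) {
    best_cor <- max(mean_cor[tied])
    tied2 <- tied[mean_cor[tied] == best_cor]
    if (length(tied2) > 1L) {
      warning("exact vote and mean-correlation tie; breaking alphabetically: ",
              paste(tied2, collapse = ", "))
    }
    call <- tied2[1L]
  } else {
    call <- tied
  }
  others <- mean_cor[setdiff(subtypes, call)]
  ord <- order(others, decreasing = TRUE)
  second <- names(others)[ord[1L]]
  # an exact tie between the 2nd and 3rd mean correlation leaves the
  # second-best subtype ambiguous
  if (length(others) > 1L && others[ord[1L]] == others[ord[2L]]) {
    second <- NA_character_
  }
  delta <- if (is.na(second)) NA_real_ else unname(mean_cor[call] - mean_cor[second])
  list(call = call, second = second, delta = delta)
}

#' Ensemble nearest-centroid classification
#'
#' Classifies every sample once per reference set (each set contributing its
#' own gene-centering vector), producing \code{n_sets} Spearman correlations
#' to each centroid. The called subtype \code{pam50_nc} is the majority vote
#' over the runs (ties break to the higher mean correlation, then
#' alphabetically with a warning). Per-centroid correlations are averaged
#' over the runs; the second-best subtype \code{pam50_nc_2nd} is the highest
#' mean correlation among the four non-called subtypes, with an exact
#' 2nd/3rd tie reported as ambiguous (\code{NA}). \code{delta} is the mean
#' correlation difference between called and second-best subtype.
#'
#' @param expr FPKM matrix, genes x samples.
#' @param refsets A \code{reference_sets} object.
#' @param centroids Centroid matrix, genes x subtypes.
#' @return Data.frame of class \code{ensemble_classification}: sample_id,
#'   pam50_nc, pam50_nc_2nd, delta, mean_cor_* and votes_* per subtype.
#'   Samples degenerate in any run carry \code{NA} calls.
#' @export
classify_ensemble <- function(expr, refsets, centroids) {
  shared <- Reduce(intersect, list(rownames(expr), rownames(refsets$centering),
                                   rownames(centroids)))
  if (length(shared) < 3L) stop("fewer than 3 genes shared with centroids/centering")
  subtypes <- colnames(centroids)
  n <- ncol(expr)
  L <- log2_fpkm(expr[shared, , drop = FALSE])
  ctr <- centroids[shared, , drop = FALSE]
  cor_sum <- matrix(0, nrow = n, ncol = length(subtypes),
                    dimnames = list(colnames(expr), subtypes))
  votes <- matrix(0L, nrow = n, ncol = length(subtypes),
                  dimnames = list(colnames(expr), subtypes))
  degenerate <- rep(FALSE, n)
  for (i in seq_len(refsets$n_sets)) {
    centered <- L - refsets$centering[shared, i]
    rho <- suppressWarnings(stats::cor(centered, ctr, method = "spearman"))
    bad <- !stats::complete.cases(rho)
    degenerate <- degenerate | bad
    rho[bad, ] <- 0
    cor_sum <- cor_sum + rho
    win <- max.col(rho, ties.method = "first")
    votes[cbind(seq_len(n), win)] <- votes[cbind(seq_len(n), win)] + 1L
  }
  if (any(degenerate)) {
    warning("degenerate profile(s) excluded: ",
            paste(colnames(expr)[degenerate], collapse = ", "))
  }
  mean_cor <- cor_sum / refsets$n_sets

  out <- data.frame(sample_id = colnames(expr), pam50_nc = NA_character_,
                    pam50_nc_2nd = NA_character_, delta = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(n)) {
    if (degenerate[j]) next
    s <- summarize_ensemble(votes[j, ], mean_cor[j, ], refsets$n_sets)
    out$pam50_nc[j] <- s$call
    out$pam50_nc_2nd[j] <- s$second
    out$delta[j] <- s$delta
  }
  mc <- as.data.frame(mean_cor)
  names(mc) <- paste0("mean_cor_", subtypes)
  vt <- as.data.frame(votes)
  names(vt) <- paste0("votes_", subtypes)
  out <- cbind(out, mc, vt)
  rownames(out) <- NULL
  class(out) <- c("ensemble_classification", "data.frame")
  out
}

#' Cross-tabulate called versus second-best subtype
#'
#' 5x5 contingency tables of \code{pam50_nc} against \code{pam50_nc_2nd},
#' overall and (optionally) per clinical subgroup. Samples with an ambiguous
#' second-best subtype are excluded from the tables and counted separately.
#'
#' @param cls An \code{ensemble_classification}.
#' @param grouping Optional clinical subgroup per sample (aligned with
#'   \code{cls}).
#' @return List with \code{overall} (5x5 table, zero diagonal),
#'   \code{by_subgroup} (named list of tables, if grouping given) and
#'   \code{n_ambiguous}.
#' @export
crosstab_nc_vs_2nd <- function(cls, grouping = NULL) {
  lv <- pam50_subtypes()
  usable <- !is.na(cls$pam50_nc) & !is.na(cls$pam50_nc_2nd)
  tab <- function(idx) {
    table(factor(cls$pam50_nc[idx], levels = lv),
          factor(cls$pam50_nc_2nd[idx], levels = lv))
  }
  out <- list(overall = tab(usable),
              n_ambiguous = sum(!is.na(cls$pam50_nc) & is.na(cls$pam50_nc_2nd)))
  if (!is.null(grouping)) {
    out$by_subgroup <- lapply(split(seq_len(nrow(cls))[usable], grouping[usable]),
                              tab)
  }
  out
}
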