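test_that("single-sample classification matches hand-computed Spearman toys", {
  # centered profile (1..5): centroid A ascending -> rho +1, B descending -> -1
  genes <- paste0("g", 1:5)
  x <- 1:5
  fpkm <- stats::setNames(2^x - 0.1, genes)         # log2(FPKM+0.1) = 1..5
  centering <- stats::setNames(rep(0, 5), genes)
  centroids <- cbind(A = c(0.1, 0.2, 0.3, 0.4, 0.5),
                     B = c(0.5, 0.4, 0.3, 0.2, 0.1))
  rownames(centroids) <- genes
  res <- classify_single(fpkm, centering, centroids)
  expect_equal(unname(res$correlations), c(1, -1))
  expect_identical(res$call, "A")

  # identity: centered profile exactly equal to the LumA centroid row
  C <- synthetic_pam50_centroids()
  zero_ctr <- stats::setNames(rep(0, nrow(C)), rownames(C))
  luma_fpkm <- stats::setNames(2^C[, "LumA"] - 0.1, rownames(C))
  res <- classify_single(luma_fpkm, zero_ctr, C)
  expect_identical(res$call, "LumA")
  expect_equal(unname(res$correlations["LumA"]), 1)
})

test_that("the argmax is returned with no minimum correlation cut-off", {
  genes <- paste0("g", 1:5)
  fpkm <- stats::setNames(2^(1:5) - 0.1, genes)
  centering <- stats::setNames(rep(0, 5), genes)
  # both centroids anti-correlated with the profile; B slightly less so
  centroids <- cbind(A = c(5, 4, 3, 2, 1), B = c(4, 5, 3, 2, 1))
  rownames(centroids) <- genes
  res <- classify_single(fpkm, centering, centroids)
  expect_true(all(res$correlations < 0))
  expect_identical(res$call, "B")
})

test_that("degenerate and under-sized profiles are handled", {
  genes <- paste0("g", 1:5)
  centering <- stats::setNames(rep(0, 5), genes)
  centroids <- cbind(A = 1:5, B = 5:1)
  rownames(centroids) <- genes
  expect_error(classify_single(c(g1 = 1, g2 = 2), centering, centroids),
               "fewer than 3 genes")
  flat <- stats::setNames(rep(2^3 - 0.1, 5), genes)
  expect_warning(res <- classify_single(flat, centering, centroids), "degenerate")
  expect_true(res$degenerate)
  expect_true(is.na(res$call))
})

test_that("classification oracle equivalence on random instances", {
  set.seed(99)
  for (i in 1:10) {
    genes <- paste0("g", 1:10)
    fpkm <- stats::setNames(2^stats::rnorm(10, 3, 1.5), genes)
    centering <- stats::setNames(stats::rnorm(10, 3, 0.5), genes)
    centroids <- matrix(stats::rnorm(50), 10,
                        dimnames = list(genes, pam50_subtypes()))
    got <- classify_single(fpkm, centering, centroids)
    want <- brute_nc(fpkm, centering, centroids)
    expect_equal(got$correlations, want$correlations, tolerance = 1e-12)
    expect_identical(got$call, want$call)
  }
})

test_that("reference set construction is balanced, seeded and guarded", {
  C <- synthetic_pam50_centroids()
  proto <- prototype_cohort(C, n_per = 1)
  # one prototype per subtype forces every set to be the full cohort
  rs <- build_reference_sets(proto$expr, proto$labels,
                             composition = stats::setNames(rep(1L, 5), pam50_subtypes()),
                             n_sets = 3, seed = 1)
  expect_length(rs$sets, 3L)
  for (s in rs$sets) expect_setequal(s, colnames(proto$expr))
  med <- apply(log2(proto$expr + 0.1), 1, stats::median)
  expect_equal(rs$centering[, 1], med)
  expect_equal(rs$centering[, 2], med)

  coh <- prototype_cohort(C, n_per = 8, noise_sd = 0.3, seed = 2)
  a <- build_reference_sets(coh$expr, coh$labels, n_sets = 10, seed = 5)
  b <- build_reference_sets(coh$expr, coh$labels, n_sets = 10, seed = 5)
  expect_identical(a$sets, b$sets)
  expect_identical(a$centering, b$centering)

  expect_error(
    build_reference_sets(coh$expr, coh$labels,
                         composition = c(Basal = 10L), n_sets = 2),
    "Basal")
})

test_that("vote and second-best summarization follows the documented rules", {
  mc <- c(Basal = 0.1, HER2E = 0.2, LumA = 0.8, LumB = 0.7, Normal = 0.3)
  v <- c(Basal = 0, HER2E = 0, LumA = 90, LumB = 10, Normal = 0)
  s <- pamstab:::summarize_ensemble(v, mc, 100)
  expect_identical(s$call, "LumA")
  expect_identical(s$second, "LumB")
  expect_equal(s$delta, 0.1)

  # vote tie breaks to the higher mean correlation
  v <- c(Basal = 0, HER2E = 0, LumA = 50, LumB = 50, Normal = 0)
  mc <- c(Basal = 0.1, HER2E = 0.2, LumA = 0.62, LumB = 0.60, Normal = 0.3)
  expect_identical(pamstab:::summarize_ensemble(v, mc, 100)$call, "LumA")

  # full tie falls back to alphabetical order with a warning
  mc2 <- c(Basal = 0.1, HER2E = 0.2, LumA = 0.6, LumB = 0.6, Normal = 0.3)
  expect_warning(s <- pamstab:::summarize_ensemble(v, mc2, 100), "alphabetically")
  expect_identical(s$call, "LumA")

  # exact 2nd/3rd mean-correlation tie -> ambiguous second-best
  v <- c(Basal = 0, HER2E = 0, LumA = 100, LumB = 0, Normal = 0)
  mc3 <- c(Basal = 0.1, HER2E = 0.3, LumA = 0.8, LumB = 0.3, Normal = 0.2)
  s <- pamstab:::summarize_ensemble(v, mc3, 100)
  expect_true(is.na(s$second))
  expect_true(is.na(s$delta))
})

test_that("ensemble collapses to the single classifier with identical sets", {
  C <- synthetic_pam50_centroids()
  coh <- prototype_cohort(C, n_per = 4, noise_sd = 0.5, seed = 12)
  med <- apply(log2(coh$expr + 0.1), 1, stats::median)
  rs <- constant_refsets(med, 10)
  cls <- classify_ensemble(coh$expr, rs, C)
  for (j in seq_len(ncol(coh$expr))) {
    single <- classify_single(coh$expr[, j], med, C)
    expect_identical(cls$pam50_nc[j], single$call)
    expect_equal(unname(as.numeric(cls[j, paste0("mean_cor_", pam50_subtypes())])),
                 unname(single$correlations), tolerance = 1e-12)
  }
  expect_true(all(as.matrix(cls[, paste0("votes_", pam50_subtypes())]) %in% c(0L, 10L)))
})

test_that("ensemble votes sum to n_sets and delta is non-negative", {
  C <- synthetic_pam50_centroids()
  coh <- prototype_cohort(C, n_per = 6, noise_sd = 0.6, seed = 21)
  rs <- build_reference_sets(coh$expr, coh$labels, n_sets = 20, seed = 3)
  cls <- classify_ensemble(coh$expr, rs, C)
  votes <- as.matrix(cls[, paste0("votes_", pam50_subtypes())])
  expect_true(all(rowSums(votes) == 20L))
  expect_true(all(cls$delta[!is.na(cls$delta)] >= 0))
  expect_true(all(cls$pam50_nc != cls$pam50_nc_2nd, na.rm = TRUE))
})

test_that("jointly rescaling cohort and reference samples leaves calls unchanged", {
  C <- synthetic_pam50_centroids()
  coh <- prototype_cohort(C, n_per = 5, noise_sd = 0.2, seed = 31)
  rs1 <- build_reference_sets(coh$expr, coh$labels, n_sets = 10, seed = 4)
  cls1 <- classify_ensemble(coh$expr, rs1, C)
  scaled <- coh$expr * 2
  rs2 <- build_reference_sets(scaled, coh$labels, n_sets = 10, seed = 4)
  cls2 <- classify_ensemble(scaled, rs2, C)
  expect_identical(cls1$pam50_nc, cls2$pam50_nc)
})

test_that("centroid inter-correlation matches the direct Pearson formula", {
  C <- synthetic_pam50_centroids()
  P <- centroid_intercorrelation(C)
  expect_equal(diag(P), stats::setNames(rep(1, 5), pam50_subtypes()))
  expect_equal(P, t(P))
  for (a in 1:5) for (b in 1:5) {
    expect_equal(P[a, b], brute_pearson(C[, a], C[, b]), tolerance = 1e-12)
  }
  toy <- cbind(A = c(1, 2, 5), B = -c(1, 2, 5))
  expect_equal(centroid_intercorrelation(toy)["A", "B"], -1)
})

test_that("cross-tabulation conserves counts with a zero diagonal", {
  cls <- data.frame(sample_id = c("a", "b", "c"),
                    pam50_nc = c("LumA", "LumA", "LumA"),
                    pam50_nc_2nd = c("LumB", "LumB", "LumB"),
                    stringsAsFactors = FALSE)
  ct <- crosstab_nc_vs_2nd(cls)
  expect_identical(as.integer(ct$overall["LumA", "LumB"]), 3L)
  expect_identical(sum(ct$overall), 3L)

  C <- synthetic_pam50_centroids()
  coh <- prototype_cohort(C, n_per = 8, noise_sd = 0.5, seed = 17)
  rs <- build_reference_sets(coh$expr, coh$labels, n_sets = 15, seed = 2)
  cls2 <- classify_ensemble(coh$expr, rs, C)
  ct2 <- crosstab_nc_vs_2nd(cls2)
  expect_true(all(diag(ct2$overall) == 0))
  usable <- !is.na(cls2$pam50_nc_2nd)
  expect_equal(as.integer(rowSums(ct2$overall)),
               as.integer(table(factor(cls2$pam50_nc[usable],
                                       levels = pam50_subtypes()))))
})
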