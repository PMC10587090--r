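make_sweep_inputs <- function(n_per = 5, noise_sd = 0, n_sets = 10, seed = 3) {
  C <- synthetic_pam50_centroids()
  part <- pam50_fixture_partition()
  core <- core_gene_universe(part)
  coh <- prototype_cohort(C, n_per = n_per, noise_sd = noise_sd, seed = seed)
  expr <- coh$expr[core, , drop = FALSE]
  centroids <- C[core, , drop = FALSE]
  rs <- build_reference_sets(expr, coh$labels, n_sets = n_sets, seed = seed,
                             composition = stats::setNames(rep(min(n_per, 5L), 5),
                                                           pam50_subtypes()))
  cls <- classify_ensemble(expr, rs, centroids)
  list(C = centroids, part = part, expr = expr, rs = rs, cls = cls,
       labels = coh$labels)
}

test_that("gene-set exclusion reduces all three matrices identically", {
  inp <- make_sweep_inputs()
  # the 45-gene core background loses the FGFR4 singleton -> 44 genes
  red <- exclude_gene_set(inp$C, inp$rs, inp$expr, inp$part, 7L)
  expect_identical(nrow(red$centroids), 44L)
  expect_identical(nrow(red$expr), 44L)
  expect_identical(nrow(red$refsets$centering), 44L)
  expect_identical(rownames(red$centroids), rownames(red$expr))
  expect_identical(rownames(red$centroids), rownames(red$refsets$centering))
  expect_false("FGFR4" %in% rownames(red$expr))

  expect_error(exclude_gene_set(inp$C, inp$rs, inp$expr, inp$part, 99L),
               "no such gene set")

  # identity perturbation: the core background is untouched
  red0 <- exclude_gene_set(inp$C, inp$rs, inp$expr, inp$part, 0L)
  expect_identical(rownames(red0$expr), rownames(inp$expr))
  expect_equal(red0$centroids, inp$C[rownames(red0$centroids), ])
})

test_that("unassigned genes are outside the sweep's background", {
  inp <- make_sweep_inputs()
  full_expr <- prototype_cohort(synthetic_pam50_centroids(), n_per = 2)$expr
  red <- exclude_gene_set(synthetic_pam50_centroids(), inp$rs, full_expr,
                          inp$part, 0L)
  expect_false(any(c("MYC", "MMP11", "BAG1", "MDM2", "BLVRA") %in%
                     rownames(red$expr)))
  expect_identical(nrow(red$expr), 45L)
})

test_that("the switch rule sits exactly at the half-votes boundary", {
  v <- c(Basal = 0, HER2E = 0, LumA = 50, LumB = 50, Normal = 0)
  expect_true(call_switch(v, "LumA", 100))
  v <- c(Basal = 0, HER2E = 0, LumA = 51, LumB = 49, Normal = 0)
  expect_false(call_switch(v, "LumA", 100))
  v <- c(Basal = 50, HER2E = 0, LumA = 0, LumB = 50, Normal = 0)
  expect_true(call_switch(v, "LumA", 100))
  expect_error(call_switch(v, "LumA", 99), "sum to n_sets")
})

test_that("the identity perturbation reproduces the original classification", {
  inp <- make_sweep_inputs(noise_sd = 0.4)
  pcls <- perturb_classify(inp$expr, inp$rs, inp$C, inp$part, 0L)
  expect_identical(pcls$pam50_nc, inp$cls$pam50_nc)
  expect_equal(pcls[paste0("mean_cor_", pam50_subtypes())],
               inp$cls[paste0("mean_cor_", pam50_subtypes())])
  # hence zero switches for every sample
  vt <- as.matrix(pcls[, paste0("votes_", pam50_subtypes())])
  nc_votes <- vt[cbind(seq_len(nrow(pcls)), match(inp$cls$pam50_nc, pam50_subtypes()))]
  expect_true(all(nc_votes > inp$rs$n_sets %/% 2))
})

test_that("zero-noise sweep matches the brute-force oracle; Basal is resistant", {
  inp <- make_sweep_inputs(n_per = 5, noise_sd = 0)
  sw <- perturbation_sweep(inp$expr, inp$rs, inp$C, inp$part, inp$cls)
  expect_identical(nrow(sw$records), nrow(inp$cls) * 7L)

  # with one prototype clone per subtype and forced full reference draws,
  # every reference set is identical, so the brute-force single call on the
  # reduced matrices predicts the whole perturbed ensemble
  for (k in 1:7) {
    red <- exclude_gene_set(inp$C, inp$rs, inp$expr, inp$part, k)
    for (sid in colnames(inp$expr)) {
      want <- brute_nc(red$expr[, sid],
                       red$refsets$centering[, 1], red$centroids)
      rec <- sw$records[sw$records$gene_set_id == k &
                          sw$records$sample_id == sid, ]
      expect_identical(rec$pam50_perturb, want$call)
      nc <- inp$cls$pam50_nc[inp$cls$sample_id == sid]
      expect_identical(rec$switch, want$call != nc)
    }
  }

  # Basal prototypes never switch under any single-set exclusion
  basal_ids <- names(inp$labels)[inp$labels == "Basal"]
  basal_rec <- sw$records[sw$records$sample_id %in% basal_ids, ]
  expect_false(any(basal_rec$switch))
  expect_true(all(basal_rec$pam50_perturb == "Basal"))
  expect_true(all(sw$k0$k0[sw$k0$sample_id %in% basal_ids]))

  # removing the ERBB2/GRB7 amplicon set destroys the HER2E prototype call
  her2_ids <- names(inp$labels)[inp$labels == "HER2E"]
  amp <- sw$records[sw$records$sample_id %in% her2_ids &
                      sw$records$gene_set_id == 4L, ]
  expect_true(all(amp$switch))
})

test_that("sweep records respect the switch/call consistency invariants", {
  inp <- make_sweep_inputs(n_per = 8, noise_sd = 0.8, n_sets = 15, seed = 44)
  sw <- perturbation_sweep(inp$expr, inp$rs, inp$C, inp$part, inp$cls)
  rec <- sw$records
  nc <- inp$cls$pam50_nc[match(rec$sample_id, inp$cls$sample_id)]
  # no switch implies the perturbed majority equals the original call
  expect_true(all(rec$pam50_perturb[!rec$switch] == nc[!rec$switch]))
  # vote counts always sum to n_sets
  vt <- as.matrix(rec[, paste0("votes_", pam50_subtypes())])
  expect_true(all(rowSums(vt) == inp$rs$n_sets))
  # K0 definition: flagged iff no record of the sample switches
  for (sid in sw$k0$sample_id) {
    expect_identical(sw$k0$k0[sw$k0$sample_id == sid],
                     !any(rec$switch[rec$sample_id == sid]))
  }
  # K0 count is monotone non-increasing as sets are added to the sweep
  k0_counts <- vapply(1:7, function(m) {
    swm <- perturbation_sweep(inp$expr, inp$rs, inp$C, inp$part, inp$cls,
                              gene_set_ids = seq_len(m))
    sum(swm$k0$k0)
  }, numeric(1))
  expect_true(all(diff(k0_counts) <= 0))
})

test_that("switch summaries equal a brute-force recount of the records", {
  inp <- make_sweep_inputs(n_per = 8, noise_sd = 0.8, n_sets = 15, seed = 44)
  sw <- perturbation_sweep(inp$expr, inp$rs, inp$C, inp$part, inp$cls)
  grouping <- rep(c("G1", "G2"), length.out = nrow(inp$cls))
  summ <- switch_summary(sw$records, inp$cls, grouping)

  sp <- summ$switch_proportions
  for (i in seq_len(nrow(sp))) {
    ids <- inp$cls$sample_id[inp$cls$pam50_nc == sp$pam50_nc[i] &
                               grouping == sp$subgroup[i]]
    rec <- sw$records[sw$records$sample_id %in% ids &
                        sw$records$gene_set_id == sp$gene_set_id[i], ]
    expect_identical(sp$n[i], nrow(rec))
    expect_identical(sp$n_switch[i], sum(rec$switch))
    expect_equal(sp$prop_switch[i], mean(rec$switch))
  }
  expect_true(all(sp$prop_switch >= 0 & sp$prop_switch <= 1, na.rm = TRUE))

  m2 <- summ$matches_2nd
  if (nrow(m2)) {
    expect_true(all(m2$prop_matches_2nd >= 0 & m2$prop_matches_2nd <= 1))
  }
  # simple stratum arithmetic: 1 switcher among 4 -> 0.25
  toy_records <- data.frame(sample_id = paste0("s", 1:4), gene_set_id = 1L,
                            pam50_perturb = c("LumB", "LumA", "LumA", "LumA"),
                            switch = c(TRUE, FALSE, FALSE, FALSE),
                            corr_delta = 0, matches_2nd = c(TRUE, NA, NA, NA))
  toy_cls <- data.frame(sample_id = paste0("s", 1:4), pam50_nc = "LumA",
                        pam50_nc_2nd = "LumB", stringsAsFactors = FALSE)
  ts <- switch_summary(toy_records, toy_cls)
  expect_equal(ts$switch_proportions$prop_switch, 0.25)
  expect_equal(ts$matches_2nd$prop_matches_2nd, 1.0)
})
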