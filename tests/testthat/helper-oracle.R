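# Independent brute-force oracle for nearest-centroid classification:
# explicit mid-rank computation, explicit median, explicit Pearson-on-ranks.
# Shares no code path with the package implementation.

brute_rank <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (1 + sum(x == x[i])) / 2
  }, numeric(1))
}

brute_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

brute_pearson <- function(a, b) {
  am <- a - sum(a) / length(a)
  bm <- b - sum(b) / length(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

brute_spearman <- function(a, b) brute_pearson(brute_rank(a), brute_rank(b))

# full nearest-centroid call: log2(FPKM+0.1), subtract centering, Spearman
# against every centroid column, first-maximum argmax
brute_nc <- function(fpkm, centering, centroids) {
  centered <- log2(fpkm + 0.1) - centering
  rho <- apply(centroids, 2, function(cc) brute_spearman(centered, cc))
  list(correlations = rho, call = names(rho)[which.max(rho)])
}

# cohort of exact subtype prototypes: FPKM = 2^(centroid + noise + baseline) - 0.1
prototype_cohort <- function(centroids, n_per = 5, noise_sd = 0, baseline = 3,
                             seed = 1) {
  set.seed(seed)
  subtype <- rep(colnames(centroids), each = n_per)
  x <- centroids[, subtype, drop = FALSE] +
    matrix(stats::rnorm(nrow(centroids) * length(subtype), sd = noise_sd),
           nrow = nrow(centroids))
  fpkm <- pmax(2^(x + baseline) - 0.1, 0)
  colnames(fpkm) <- sprintf("P%03d", seq_along(subtype))
  list(expr = fpkm, labels = stats::setNames(subtype, colnames(fpkm)))
}

# reference sets that all share one explicit centering vector
constant_refsets <- function(centering, n_sets) {
  structure(list(sets = replicate(n_sets, character(), simplify = FALSE),
                 centering = matrix(centering, nrow = length(centering),
                                    ncol = n_sets,
                                    dimnames = list(names(centering), NULL)),
                 n_sets = as.integer(n_sets), statistic = "median"),
            class = "reference_sets")
}
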