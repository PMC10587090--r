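#' Default clinical subgroup proportions
#'
#' Population-based proportions of the four ER/PR/HER2 subgroups used as
#' simulator defaults: TNBC 10.3%, ERnHER2p 4.1%, ERpHER2p 8.8%,
#' ERpHER2n 76.8%.
#'
#' @return Named numeric vector summing to 1.
#' @export
default_subgroup_proportions <- function() {
  p <- c(TNBC = 0.103, ERnHER2p = 0.041, ERpHER2p = 0.088, ERpHER2n = 0.768)
  p / sum(p)
}

#' Default conditional subtype-given-subgroup table
#'
#' PAM50 subtype composition within each clinical subgroup, matching the
#' observed population frequencies (for example 73.3% of TNBC tumors are
#' Basal). Rows are renormalized to sum to exactly 1, absorbing the rounding
#' of the printed percentages.
#'
#' @return Matrix, subgroups x subtypes, rows summing to 1.
#' @export
default_subtype_given_subgroup <- function() {
  m <- rbind(
    TNBC     = c(Basal = 0.733, HER2E = 0.154, LumA = 0.034, LumB = 0.008, Normal = 0.071),
    ERnHER2p = c(0.130, 0.772, 0.028, 0.008, 0.063),
    ERpHER2p = c(0.015, 0.352, 0.243, 0.340, 0.051),
    ERpHER2n = c(0.015, 0.018, 0.626, 0.278, 0.064)
  )
  colnames(m) <- pam50_subtypes()
  sweep(m, 1, rowSums(m), "/")
}

#' Default per-subtype survival hazards
#'
#' Exponential hazards per day for overall survival (OS) and distant
#' recurrence-free interval (DRFI), ordered LumA best / Basal worst,
#' yielding realistic 10-year outcome levels for an early-stage cohort.
#'
#' @return List with numeric vectors \code{os} and \code{drfi} (per day),
#'   named by subtype.
#' @export
default_subtype_hazards <- function() {
  per_year <- function(x) x / 365.25
  list(
    os = per_year(c(Basal = 0.065, HER2E = 0.055, LumA = 0.020,
                    LumB = 0.050, Normal = 0.030)),
    drfi = per_year(c(Basal = 0.055, HER2E = 0.045, LumA = 0.012,
                      LumB = 0.040, Normal = 0.020))
  )
}

#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic cohort generator.
#'
#' @param n_samples Number of tumors to simulate.
#' @param subgroup_proportions Named fractions over clinical subgroups
#'   (must sum to 1 within 1e-9).
#' @param subtype_given_subgroup Conditional probability table, subgroups x
#'   subtypes; every row must sum to 1 within 1e-9.
#' @param noise_sd SD of additive Gaussian noise on the centered-log
#'   expression scale (log2 units).
#' @param library_scale_sd SD of the per-sample log2-scale library-size
#'   jitter (a shared shift of all genes in a sample).
#' @param baseline Per-gene baseline b on the log2 scale added before
#'   converting to FPKM; a single number is recycled over genes.
#' @param hazard_os,hazard_drfi Named per-day exponential hazards by subtype.
#' @param censor_rate Expected fraction of administratively censored
#'   follow-up per subtype (independent exponential censoring).
#' @param seed Integer seed; mandatory for reproducible cohorts.
#' @return A validated list of class \code{simulation_config}.
#' @export
simulation_config <- function(n_samples = 600L,
                              subgroup_proportions = default_subgroup_proportions(),
                              subtype_given_subgroup = default_subtype_given_subgroup(),
                              noise_sd = 0.4,
                              library_scale_sd = 0.15,
                              baseline = 3,
                              hazard_os = default_subtype_hazards()$os,
                              hazard_drfi = default_subtype_hazards()$drfi,
                              censor_rate = 0.7,
                              seed = 1L) {
  if (abs(sum(subgroup_proportions) - 1) > 1e-9) {
    stop("subgroup_proportions must sum to 1")
  }
  if (any(subgroup_proportions < 0)) stop("subgroup_proportions must be >= 0")
  if (is.null(rownames(subtype_given_subgroup)) ||
      !all(names(subgroup_proportions) %in% rownames(subtype_given_subgroup))) {
    stop("subtype_given_subgroup needs a row for every subgroup")
  }
  bad <- which(abs(rowSums(subtype_given_subgroup) - 1) > 1e-9)
  if (length(bad)) stop("subtype_given_subgroup rows must sum to 1: ",
                        paste(rownames(subtype_given_subgroup)[bad], collapse = ", "))
  if (noise_sd < 0 || library_scale_sd < 0) stop("noise SDs must be >= 0")
  for (h in list(hazard_os, hazard_drfi)) {
    if (any(h <= 0)) stop("hazards must be > 0")
  }
  if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must be in [0, 1)")
  structure(list(n_samples = as.integer(n_samples),
                 subgroup_proportions = subgroup_proportions,
                 subtype_given_subgroup = subtype_given_subgroup,
                 noise_sd = noise_sd, library_scale_sd = library_scale_sd,
                 baseline = baseline, hazard_os = hazard_os,
                 hazard_drfi = hazard_drfi, censor_rate = censor_rate,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# statuses consistent with the drawn subgroup (derive_clinical_subgroup
# round-trips to the subgroup for every assignment made here)
assign_markers <- function(subgroup, n) {
  er <- pr <- her2 <- rep("negative", n)
  er[subgroup %in% c("ERpHER2p", "ERpHER2n")] <- "positive"
  her2[subgroup %in% c("ERnHER2p", "ERpHER2p")] <- "positive"
  pr_pos <- stats::runif(n) < ifelse(subgroup == "ERpHER2n", 0.85,
                             ifelse(subgroup == "ERpHER2p", 0.70, 0))
  pr[pr_pos] <- "positive"
  data.frame(er_status = er, pr_status = pr, her2_status = her2,
             stringsAsFactors = FALSE)
}

#' Simulate survival endpoints from subtype-specific hazards
#'
#' Event times are exponential with the configured per-subtype hazard;
#' censoring is an independent exponential whose per-subtype rate is chosen
#' so the expected censored fraction equals \code{censor_rate}
#' (\eqn{\mu = c/(1-c)\,\lambda}). Observed time is the minimum; the event
#' indicator is 1 when the event precedes censoring.
#'
#' @param subtypes Character vector of generating subtypes, one per sample.
#' @param hazards Named per-day hazards covering every subtype present.
#' @param censor_rate Expected censored fraction in [0, 1).
#' @return Data.frame with columns \code{time} (days) and \code{event} (0/1).
#' @export
simulate_survival <- function(subtypes, hazards, censor_rate = 0.7) {
  missing <- setdiff(unique(subtypes), names(hazards))
  if (length(missing)) stop("no hazard configured for subtype(s): ",
                            paste(missing, collapse = ", "))
  lam <- hazards[subtypes]
  if (any(lam <= 0)) stop("hazards must be > 0")
  t_event <- stats::rexp(length(subtypes), rate = lam)
  if (censor_rate > 0) {
    mu <- censor_rate / (1 - censor_rate) * lam
    t_cens <- stats::rexp(length(subtypes), rate = mu)
  } else {
    t_cens <- rep(Inf, length(subtypes))
  }
  data.frame(time = round(pmin(t_event, t_cens), 1),
             event = as.integer(t_event <= t_cens))
}

#' Simulate a synthetic breast cancer cohort
#'
#' Draws, per sample, a clinical subgroup then a PAM50 subtype from the
#' configured conditional table; builds centered-log expression as the
#' subtype centroid plus Gaussian noise; converts to linear FPKM as
#' \code{pmax(2^(x + b + s) - 0.1, 0)} with per-gene baseline b and
#' per-sample library jitter s; assigns ER/PR/HER2 consistent with the
#' subgroup, other clinical covariates, and exponential OS/DRFI endpoints.
#' Fully deterministic given \code{config$seed}.
#'
#' @param centroids Centroid matrix on the centered log scale (genes x
#'   subtypes), e.g. [synthetic_pam50_centroids()].
#' @param config A [simulation_config()].
#' @return List of class \code{synthetic_cohort} with elements
#'   \code{expression} (genes x samples FPKM matrix), \code{clinical}
#'   (clinical table), and \code{truth} (data.frame of generating subgroup
#'   and subtype per sample).
#' @export
simulate_cohort <- function(centroids, config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  if (!identical(attr(centroids, "scale"), "centered_log")) {
    stop("simulate_cohort needs centered-log centroids")
  }
  set.seed(config$seed)
  n <- config$n_samples
  genes <- rownames(centroids)
  sample_ids <- sprintf("S%04d", seq_len(n))

  subgroup <- sample(names(config$subgroup_proportions), n, replace = TRUE,
                     prob = config$subgroup_proportions)
  subtype <- vapply(subgroup, function(g) {
    sample(colnames(config$subtype_given_subgroup), 1L,
           prob = config$subtype_given_subgroup[g, ])
  }, character(1))

  x <- centroids[, subtype, drop = FALSE] +
    matrix(stats::rnorm(length(genes) * n, sd = config$noise_sd),
           nrow = length(genes))
  b <- rep_len(config$baseline, length(genes))
  s <- stats::rnorm(n, sd = config$library_scale_sd)
  fpkm <- pmax(2^(x + b + rep(s, each = length(genes))) - 0.1, 0)
  dimnames(fpkm) <- list(genes, sample_ids)

  markers <- assign_markers(subgroup, n)
  os <- simulate_survival(subtype, config$hazard_os, config$censor_rate)
  drfi <- simulate_survival(subtype, config$hazard_drfi, config$censor_rate)
  clinical <- data.frame(
    sample_id = sample_ids,
    markers,
    nodal_status = ifelse(stats::runif(n) < 0.35, "positive", "negative"),
    endocrine_treated = markers$er_status == "positive" & stats::runif(n) < 0.9,
    age_at_diagnosis = pmin(pmax(round(stats::rnorm(n, 63, 11)), 25), 95),
    tumor_size = round(stats::rlnorm(n, log(18), 0.5)),
    histology = ifelse(stats::runif(n) < 0.10, "lobular", "other"),
    os_time = os$time, os_event = os$event,
    drfi_time = drfi$time, drfi_event = drfi$event,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(sample_id = sample_ids, subgroup = subgroup,
                      subtype = subtype, stringsAsFactors = FALSE,
                      row.names = NULL)
  structure(list(expression = fpkm,
                 clinical = validate_clinical_table(clinical),
                 truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d samples, %d genes\n",
              ncol(x$expression), nrow(x$expression)))
  print(table(x$truth$subgroup, x$truth$subtype))
  invisible(x)
}

#' Simulate expression with planted co-expression modules
#'
#' Generates a gene-by-sample FPKM matrix in which each configured module
#' shares one latent factor: gene g in module m has centered-log expression
#' \code{loading * z_m + noise}, genes outside any module are independent
#' noise. Used to exercise co-expression cluster recovery.
#'
#' @param n_samples Number of samples.
#' @param modules Named list of gene-symbol vectors, one entry per module.
#' @param background_genes Extra genes with no shared factor.
#' @param noise_sd SD of the per-gene noise on the log2 scale.
#' @param loading Factor loading shared by module genes.
#' @param baseline Log2-scale baseline before FPKM conversion.
#' @param seed Integer seed.
#' @return List with \code{expression} (FPKM matrix), \code{truth}
#'   (a \code{gene_partition} of the planted modules, background genes
#'   unassigned) and \code{factors} (samples x modules matrix of the latent
#'   factor draws).
#' @export
simulate_module_expression <- function(n_samples, modules,
                                       background_genes = character(),
                                       noise_sd = 0.2, loading = 1,
                                       baseline = 3, seed = 1L) {
  set.seed(seed)
  genes <- c(unlist(modules, use.names = FALSE), background_genes)
  if (anyDuplicated(genes)) stop("module gene lists must be disjoint")
  x <- matrix(stats::rnorm(length(genes) * n_samples, sd = noise_sd),
              nrow = length(genes), dimnames = list(genes, sprintf("S%04d", seq_len(n_samples))))
  assignment <- stats::setNames(rep(NA_integer_, length(genes)), genes)
  factors <- matrix(NA_real_, nrow = n_samples, ncol = length(modules),
                    dimnames = list(colnames(x),
                                    names(modules) %||% paste0("m", seq_along(modules))))
  for (k in seq_along(modules)) {
    z <- stats::rnorm(n_samples)
    factors[, k] <- z
    x[modules[[k]], ] <- x[modules[[k]], , drop = FALSE] +
      loading * rep(z, each = length(modules[[k]]))
    assignment[modules[[k]]] <- k
  }
  fpkm <- pmax(2^(x + baseline) - 0.1, 0)
  list(expression = fpkm, truth = gene_partition(assignment),
       factors = factors)
}
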