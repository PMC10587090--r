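endpoint_columns <- function(endpoint = c("os", "drfi")) {
  endpoint <- match.arg(endpoint)
  list(time = paste0(endpoint, "_time"), event = paste0(endpoint, "_event"))
}

# assemble a per-sample data.frame of time/event/stratum from a named list
# of sample-ID vectors; strata must not overlap
stratum_frame <- function(clinical, strata, endpoint) {
  ids <- unlist(strata, use.names = FALSE)
  if (anyDuplicated(ids)) stop("strata overlap: a sample may appear in only one stratum")
  cols <- endpoint_columns(endpoint)
  lab <- rep(names(strata), lengths(strata))
  idx <- match(ids, clinical$sample_id)
  if (anyNA(idx)) stop("sample(s) absent from clinical table: ",
                       paste(ids[is.na(idx)][1:min(3, sum(is.na(idx)))], collapse = ", "))
  df <- data.frame(sample_id = ids, stratum = lab,
                   time = clinical[[cols$time]][idx],
                   event = clinical[[cols$event]][idx],
                   stringsAsFactors = FALSE)
  df[!is.na(df$time) & !is.na(df$event), , drop = FALSE]
}

#' Kaplan-Meier curves and log-rank test across strata
#'
#' Estimates per-stratum survival by the Kaplan-Meier method and compares
#' strata with the two-sided log-rank test. Empty strata are dropped with a
#' warning; fewer than two usable strata is an error.
#'
#' @param clinical Clinical table with \code{os_time}/\code{os_event} and
#'   \code{drfi_time}/\code{drfi_event} columns (days, 0/1).
#' @param strata Named list of sample-ID vectors, non-overlapping.
#' @param endpoint \code{"os"} or \code{"drfi"}.
#' @return List with \code{fit} (a \code{survfit} object), \code{chisq},
#'   \code{df}, \code{p} (log-rank), \code{n} and \code{events} per stratum.
#' @export
km_logrank <- function(clinical, strata, endpoint = c("os", "drfi")) {
  endpoint <- match.arg(endpoint)
  df <- stratum_frame(clinical, strata, endpoint)
  empty <- setdiff(names(strata), unique(df$stratum))
  if (length(empty)) {
    warning("dropping empty stratum(s): ", paste(empty, collapse = ", "))
  }
  df$stratum <- factor(df$stratum, levels = setdiff(names(strata), empty))
  if (nlevels(df$stratum) < 2L) stop("log-rank test needs at least 2 usable strata")
  if (sum(df$event) == 0) stop("log-rank test needs at least one event")
  fit <- survival::survfit(survival::Surv(time, event) ~ stratum, data = df)
  sd <- survival::survdiff(survival::Surv(time, event) ~ stratum, data = df)
  dfree <- length(sd$n) - 1L
  list(fit = fit,
       chisq = unname(sd$chisq),
       df = dfree,
       p = stats::pchisq(sd$chisq, dfree, lower.tail = FALSE),
       n = table(df$stratum),
       events = tapply(df$event, df$stratum, sum))
}

#' Univariate Cox regression against a reference stratum
#'
#' Fits a proportional-hazards model with the stratum label as the only
#' covariate, using the Efron approximation for ties, and reports the
#' hazard ratio, Wald 95% confidence interval and p-value of every
#' non-reference stratum relative to the reference. Strata with zero events
#' or non-converged coefficients are flagged unstable.
#'
#' @param clinical Clinical table (see [km_logrank()]).
#' @param strata Named list of sample-ID vectors, non-overlapping.
#' @param reference_label Name of the reference stratum (must be non-empty
#'   and contain at least one event).
#' @param endpoint \code{"os"} or \code{"drfi"}.
#' @return Data.frame: stratum, n, events, hr, ci_lower, ci_upper, p,
#'   unstable.
#' @export
cox_univariate <- function(clinical, strata, reference_label,
                           endpoint = c("os", "drfi")) {
  endpoint <- match.arg(endpoint)
  if (!reference_label %in% names(strata)) {
    stop("reference stratum '", reference_label, "' not among strata")
  }
  df <- stratum_frame(clinical, strata, endpoint)
  ref <- df[df$stratum == reference_label, , drop = FALSE]
  if (!nrow(ref)) stop("reference stratum is empty")
  if (sum(ref$event) < 1) stop("reference stratum has no events")
  df$stratum <- stats::relevel(factor(df$stratum), ref = reference_label)
  fit <- survival::coxph(survival::Surv(time, event) ~ stratum, data = df,
                         ties = "efron")
  sm <- summary(fit)
  co <- sm$coefficients
  ci <- sm$conf.int
  lev <- levels(df$stratum)[-1L]
  events <- tapply(df$event, df$stratum, sum)
  n <- table(df$stratum)
  data.frame(stratum = lev,
             n = as.integer(n[lev]),
             events = as.integer(events[lev]),
             hr = unname(co[, "exp(coef)"]),
             ci_lower = unname(ci[, "lower .95"]),
             ci_upper = unname(ci[, "upper .95"]),
             p = unname(co[, "Pr(>|z|)"]),
             unstable = unname(events[lev] == 0 | !is.finite(co[, "se(coef)"]) |
                                 co[, "se(coef)"] > 10),
             row.names = NULL, stringsAsFactors = FALSE)
}
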