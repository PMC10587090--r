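#' PAM50 intrinsic subtype labels
#'
#' The five intrinsic breast cancer subtypes of the PAM50 scheme, in the
#' fixed (alphabetical) order used throughout the package for deterministic
#' tie-breaking: Basal, HER2E, LumA, LumB, Normal.
#'
#' @return Character vector of length 5.
#' @export
pam50_subtypes <- function() {
  c("Basal", "HER2E", "LumA", "LumB", "Normal")
}

#' The 50 PAM50 gene symbols
#'
#' Canonical (current HUGO) symbols for the 50 genes of the PAM50 signature.
#' Legacy symbols used in older centroid files can be translated with
#' [pam50_aliases()].
#'
#' @return Character vector of length 50, alphabetically sorted.
#' @export
pam50_genes <- function() {
  c("ACTR3B", "ANLN", "BAG1", "BCL2", "BIRC5", "BLVRA", "CCNB1",
    "CCNE1", "CDC20", "CDC6", "CDCA1", "CDH3", "CENPF", "CEP55",
    "CXXC5", "EGFR", "ERBB2", "ESR1", "EXO1", "FGFR4", "FOXA1",
    "FOXC1", "GPR160", "GRB7", "KIF2C", "KNTC2", "KRT14", "KRT17",
    "KRT5", "MAPT", "MDM2", "MELK", "MIA", "MKI67", "MLPH", "MMP11",
    "MYBL2", "MYC", "NAT1", "ORC6L", "PGR", "PHGDH", "PTTG1", "RRM2",
    "SFRP1", "SLC39A6", "TMEM45B", "TYMS", "UBE2C", "UBE2T")
}

#' Legacy-to-current PAM50 gene symbol aliases
#'
#' Maps current HUGO symbols used in some expression matrices back to the
#' legacy symbols of the original centroid files (CDCA1/NUF2, KNTC2/NDC80,
#' ORC6L/ORC6). Names are the alias, values the symbol used by this package.
#'
#' @return Named character vector.
#' @export
pam50_aliases <- function() {
  c(NUF2 = "CDCA1", NDC80 = "KNTC2", ORC6 = "ORC6L")
}

#' Derive the clinical subgroup from ER/PR/HER2 status
#'
#' Assigns each tumor to one of four therapy-relevant subgroups from its
#' estrogen receptor (ER), progesterone receptor (PR) and HER2 status:
#' \describe{
#'   \item{TNBC}{ER-negative, PR-negative, HER2-negative (triple negative)}
#'   \item{ERnHER2p}{ER-negative, HER2-positive}
#'   \item{ERpHER2p}{ER-positive, HER2-positive}
#'   \item{ERpHER2n}{ER-positive, HER2-negative}
#' }
#' PR enters only the triple-negative rule. Tumors fitting no rule (for
#' example ER-negative, PR-positive, HER2-negative) and tumors with an
#' unknown required marker are returned as \code{"unclassified"}, so
#' partially annotated cohorts still run. The function is total: every
#' input maps to exactly one label.
#'
#' @param er,pr,her2 Character vectors with values \code{"positive"},
#'   \code{"negative"} or \code{"unknown"}; recycled to a common length.
#' @return Character vector of subgroup labels.
#' @export
derive_clinical_subgroup <- function(er, pr, her2) {
  n <- max(length(er), length(pr), length(her2))
  er <- rep_len(as.character(er), n)
  pr <- rep_len(as.character(pr), n)
  her2 <- rep_len(as.character(her2), n)
  ok <- c("positive", "negative", "unknown")
  er[!er %in% ok] <- "unknown"
  pr[!pr %in% ok] <- "unknown"
  her2[!her2 %in% ok] <- "unknown"

  out <- rep("unclassified", n)
  out[er == "negative" & pr == "negative" & her2 == "negative"] <- "TNBC"
  out[er == "negative" & her2 == "positive"] <- "ERnHER2p"
  out[er == "positive" & her2 == "positive"] <- "ERpHER2p"
  out[er == "positive" & her2 == "negative"] <- "ERpHER2n"
  # every rule requires known ER and HER2; TNBC additionally requires known PR,
  # which its mask already enforces
  out[er == "unknown" | her2 == "unknown"] <- "unclassified"
  out
}

#' Clinical subgroup labels
#'
#' @return Character vector of the four named subgroups plus
#'   \code{"unclassified"}.
#' @export
clinical_subgroups <- function() {
  c("TNBC", "ERnHER2p", "ERpHER2p", "ERpHER2n", "unclassified")
}
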