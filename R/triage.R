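#' Gene panel for familial hypercholesterolemia triage
#'
#' The four "standard" FH genes, plus the broader dyslipidemia panel of
#' phenocopy genes whose variants can mimic the FH phenotype
#' (sitosterolemia, lysosomal acid lipase deficiency, cerebrotendinous
#' xanthomatosis, elevated Lp(a)).
#'
#' @param fh_genes Character vector of classic FH genes.
#' @param phenocopy_genes Character vector of phenocopy genes.
#' @return A `gene_panel` list with the two disjoint sets.
#' @export
gene_panel <- function(fh_genes = c("LDLR", "APOB", "PCSK9", "LDLRAP1"),
                       phenocopy_genes = c("ABCG5", "ABCG8", "APOE",
                                           "CYP27A1", "LIPA", "LPA")) {
  if (length(intersect(fh_genes, phenocopy_genes)) > 0L) {
    abort_fh("fh_genes and phenocopy_genes must be disjoint", "fh_panel_error")
  }
  structure(list(fh_genes = fh_genes, phenocopy_genes = phenocopy_genes),
            class = "gene_panel")
}

#' Rare-variant frequency filter
#'
#' Variants whose gnomAD PopMax filtering allele frequency exceeds the
#' estimated FH prevalence are too common to cause a dominant disorder and
#' are excluded from interpretation. The comparison is strictly greater
#' than: a FAF exactly at the threshold is retained. A missing FAF (variant
#' absent from gnomAD, i.e. novel) is retained — absence of frequency
#' evidence is not evidence of commonness.
#'
#' @param popmax_faf Numeric vector of PopMax FAF fractions (NA = absent).
#' @param threshold Fraction in (0, 1\]; default 0.005 (0.5%).
#' @return Logical vector: TRUE = keep, FALSE = discard.
#' @export
filter_by_faf <- function(popmax_faf, threshold = 0.005) {
  stopifnot(threshold > 0, threshold <= 1)
  if (any(!is.na(popmax_faf) & (popmax_faf < 0 | popmax_faf > 1))) {
    abort_fh("popmax_faf outside [0, 1]", "fh_triage_error")
  }
  is.na(popmax_faf) | popmax_faf <= threshold
}

.clinvar_plp <- c("Pathogenic", "Likely pathogenic",
                  "Pathogenic/Likely pathogenic")

#' ClinVar trust rule
#'
#' A ClinVar aggregate classification is adopted directly only when it is
#' pathogenic and/or likely pathogenic AND its review status earns trust:
#' two gold stars with at least five submitters, or three or more gold
#' stars. Anything else (including conflicting records and P/LP records
#' failing the star rules) returns NA and falls through to ACMG
#' combination. Submitters are counted across all submissions.
#'
#' @param classification ClinVar germline classification strings
#'   ("Pathogenic", "Likely pathogenic", "Pathogenic/Likely pathogenic",
#'   "VUS", "Likely benign", "Benign", "Conflicting", "absent").
#' @param gold_stars Integer 0-4 review-status stars.
#' @param submitter_count Integer number of submitters.
#' @return Character vector: "Pathogenic", "LikelyPathogenic" or
#'   "PathogenicLikelyPathogenic" where trusted, otherwise NA (no decision).
#' @export
classify_by_clinvar <- function(classification, gold_stars, submitter_count) {
  trusted <- classification %in% .clinvar_plp &
    ((gold_stars == 2 & submitter_count >= 5) | gold_stars >= 3)
  trusted[is.na(trusted)] <- FALSE
  out <- rep(NA_character_, length(classification))
  out[trusted] <- c(
    "Pathogenic" = "Pathogenic",
    "Likely pathogenic" = "LikelyPathogenic",
    "Pathogenic/Likely pathogenic" = "PathogenicLikelyPathogenic"
  )[classification[trusted]]
  out
}

#' Classify one variant through the full triage cascade
#'
#' Order of precedence: (1) the frequency filter — a too-common variant is
#' never interpreted, whatever ClinVar says; (2) the ClinVar trust rule;
#' (3) ACMG/AMP evidence combination.
#'
#' @param popmax_faf PopMax FAF fraction or NA.
#' @param classification,gold_stars,submitter_count ClinVar fields (use
#'   "absent", 0, 0 when no record exists).
#' @param criteria Comma-separated ACMG criterion string (possibly empty).
#' @param faf_threshold Frequency-filter threshold.
#' @return A list with `class` (Pathogenic / LikelyPathogenic /
#'   PathogenicLikelyPathogenic / VUS / LikelyBenign / Benign /
#'   FrequencyFiltered) and `source` (FrequencyFiltered / ClinVarRule /
#'   AcmgCombination).
#' @export
classify_variant <- function(popmax_faf, classification = "absent",
                             gold_stars = 0L, submitter_count = 0L,
                             criteria = "", faf_threshold = 0.005) {
  if (!filter_by_faf(popmax_faf, faf_threshold)) {
    return(list(class = "FrequencyFiltered", source = "FrequencyFiltered"))
  }
  cv <- classify_by_clinvar(classification, gold_stars, submitter_count)
  if (!is.na(cv)) {
    return(list(class = cv, source = "ClinVarRule"))
  }
  list(class = combine_acmg(parse_criteria(criteria)),
       source = "AcmgCombination")
}

.is_plp <- function(class) {
  class %in% c("Pathogenic", "LikelyPathogenic", "PathogenicLikelyPathogenic")
}

#' Detect a high-priority VUS
#'
#' A VUS is high-priority when it lies in a classic FH gene and is one
#' criterion short of Likely Pathogenic: adding a single Moderate OR a
#' single Supporting criterion to its evidence set would reach LP (or P).
#'
#' @param evidence An `acmg_evidence` object that combines to VUS.
#' @param gene HGNC gene symbol.
#' @param panel A [gene_panel()].
#' @return Logical.
#' @export
is_priority_vus <- function(evidence, gene, panel = gene_panel()) {
  if (!inherits(evidence, "acmg_evidence")) {
    evidence <- parse_criteria(evidence)
  }
  if (combine_acmg(evidence) != "VUS") {
    abort_fh("is_priority_vus requires evidence combining to VUS",
             "fh_triage_error")
  }
  if (!gene %in% panel$fh_genes) return(FALSE)
  plus <- function(strength) {
    aug <- acmg_evidence(c(evidence$code, "PMX"), c(evidence$strength, strength))
    combine_acmg(aug) %in% c("LikelyPathogenic", "Pathogenic")
  }
  plus("Moderate") || plus("Supporting")
}

#' Triage a joined variant table
#'
#' Runs [classify_variant()] and [is_priority_vus()] over every row of a
#' table produced by [read_tables()].
#'
#' @param joined Tibble from [read_tables()].
#' @param panel A [gene_panel()].
#' @param faf_threshold Frequency-filter threshold.
#' @return The input with columns `class`, `source`, `is_plp`,
#'   `priority_vus` appended.
#' @export
triage_variants <- function(joined, panel = gene_panel(),
                            faf_threshold = 0.005) {
  res <- lapply(seq_len(nrow(joined)), function(i) {
    classify_variant(joined$popmax_faf[i], joined$classification[i],
                     joined$gold_stars[i], joined$submitter_count[i],
                     joined$criteria[i], faf_threshold)
  })
  joined$class <- vapply(res, `[[`, character(1), "class")
  joined$source <- vapply(res, `[[`, character(1), "source")
  joined$is_plp <- .is_plp(joined$class)
  joined$priority_vus <- vapply(seq_len(nrow(joined)), function(i) {
    if (joined$class[i] != "VUS") return(FALSE)
    is_priority_vus(parse_criteria(joined$criteria[i]), joined$gene[i], panel)
  }, logical(1))
  joined
}
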