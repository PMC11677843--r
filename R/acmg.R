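#' @name acmg
#' @title ACMG/AMP evidence combination
#'
#' @description
#' Variant-level evidence items (PVS1, PS1-4, PM1-6, PP1-5 on the pathogenic
#' side; BA1, BS1-4, BP1-7 on the benign side) each carry a strength:
#' VeryStrong, Strong, Moderate, Supporting, StandAloneBenign, BenignStrong
#' or BenignSupporting. A criterion may be applied at a non-default strength
#' with a suffix, e.g. "PVS1_Strong" or "PM2_Supporting"; the modified
#' strength replaces the default, it never stacks. Each criterion code may be
#' used at most once per variant.
NULL

.acmg_strengths <- c("VeryStrong", "Strong", "Moderate", "Supporting",
                     "StandAloneBenign", "BenignStrong", "BenignSupporting")

.default_strength <- function(code) {
  prefix <- toupper(sub("[0-9].*$", "", code))
  switch(prefix,
    PVS = "VeryStrong",
    PS = "Strong",
    PM = "Moderate",
    PP = "Supporting",
    BA = "StandAloneBenign",
    BS = "BenignStrong",
    BP = "BenignSupporting",
    abort_fh(paste0("unknown ACMG criterion code '", code, "'"),
             "fh_acmg_error")
  )
}

.modifier_strength <- function(code, modifier) {
  benign <- grepl("^B", code, ignore.case = TRUE)
  m <- tolower(modifier)
  if (benign) {
    switch(m,
      standalone = "StandAloneBenign",
      strong = "BenignStrong",
      supporting = "BenignSupporting",
      abort_fh(paste0("unknown strength modifier '", modifier, "' on '",
                      code, "'"), "fh_acmg_error")
    )
  } else {
    switch(m,
      verystrong = "VeryStrong",
      strong = "Strong",
      moderate = "Moderate",
      supporting = "Supporting",
      abort_fh(paste0("unknown strength modifier '", modifier, "' on '",
                      code, "'"), "fh_acmg_error")
    )
  }
}

#' Parse a comma-separated list of ACMG criterion codes
#'
#' @param criteria A single string such as `"PVS1_Strong,PM2"`, or a
#'   character vector of codes. Empty string means no evidence.
#' @return An `acmg_evidence` tibble with columns `code` and `strength`.
#' @export
parse_criteria <- function(criteria) {
  if (length(criteria) == 1L && (is.na(criteria) || !nzchar(trimws(criteria)))) {
    items <- character(0)
  } else if (length(criteria) == 1L && grepl(",", criteria)) {
    items <- trimws(strsplit(criteria, ",", fixed = TRUE)[[1]])
  } else {
    items <- trimws(criteria)
  }
  items <- items[nzchar(items)]
  code <- sub("_.*$", "", items)
  modifier <- ifelse(grepl("_", items), sub("^[^_]*_", "", items), NA)
  strength <- character(length(items))
  for (i in seq_along(items)) {
    strength[i] <- if (is.na(modifier[i])) .default_strength(code[i])
                   else .modifier_strength(code[i], modifier[i])
  }
  acmg_evidence(code, strength)
}

#' Construct an ACMG evidence set
#'
#' @param code Character vector of criterion codes (e.g. "PVS1", "PM2").
#' @param strength Character vector of effective strengths, from
#'   VeryStrong, Strong, Moderate, Supporting, StandAloneBenign,
#'   BenignStrong, BenignSupporting.
#' @return An `acmg_evidence` tibble.
#' @export
acmg_evidence <- function(code = character(0), strength = character(0)) {
  stopifnot(length(code) == length(strength))
  bad <- setdiff(strength, .acmg_strengths)
  if (length(bad) > 0L) {
    abort_fh(paste0("unknown evidence strength: ", paste(bad, collapse = ", ")),
             "fh_acmg_error")
  }
  if (anyDuplicated(toupper(code))) {
    abort_fh("each ACMG criterion code may appear at most once",
             "fh_acmg_error")
  }
  out <- tibble::tibble(code = toupper(code), strength = strength)
  class(out) <- c("acmg_evidence", class(out))
  out
}

# strength tallies used by every combination rule
.evidence_counts <- function(evidence) {
  s <- factor(evidence$strength, levels = .acmg_strengths)
  tab <- table(s)
  list(vs = tab[["VeryStrong"]], s = tab[["Strong"]], m = tab[["Moderate"]],
       p = tab[["Supporting"]], ba = tab[["StandAloneBenign"]],
       bs = tab[["BenignStrong"]], bp = tab[["BenignSupporting"]])
}

#' Combine ACMG/AMP evidence into a five-tier classification
#'
#' Applies the standard combining rules over the effective strengths.
#' Pathogenic: 1 VeryStrong with (>=1 Strong, >=2 Moderate, 1 Moderate +
#' 1 Supporting, or >=2 Supporting); >=2 VeryStrong; >=2 Strong; or 1 Strong
#' with (>=3 Moderate, 2 Moderate + >=2 Supporting, or 1 Moderate +
#' >=4 Supporting). Likely pathogenic: 1 VeryStrong + >=1 Moderate; 1 Strong
#' + 1-2 Moderate; 1 Strong + >=2 Supporting; >=3 Moderate; 2 Moderate +
#' >=2 Supporting; or 1 Moderate + >=4 Supporting. Benign: StandAlone or
#' >=2 BenignStrong. Likely benign: 1 BenignStrong + >=1 BenignSupporting,
#' or >=2 BenignSupporting. When rules on both sides fire, or none fires,
#' the call is VUS.
#'
#' @param evidence An `acmg_evidence` object (see [acmg_evidence()],
#'   [parse_criteria()]).
#' @return One of "Pathogenic", "LikelyPathogenic", "VUS", "LikelyBenign",
#'   "Benign".
#' @export
combine_acmg <- function(evidence) {
  if (!inherits(evidence, "acmg_evidence")) {
    evidence <- acmg_evidence(evidence$code, evidence$strength)
  }
  n <- .evidence_counts(evidence)

  pathogenic <-
    (n$vs >= 1 && (n$s >= 1 || n$m >= 2 || (n$m >= 1 && n$p >= 1) || n$p >= 2)) ||
    n$vs >= 2 ||
    n$s >= 2 ||
    (n$s == 1 && (n$m >= 3 || (n$m == 2 && n$p >= 2) || (n$m == 1 && n$p >= 4)))
  likely_pathogenic <-
    (n$vs == 1 && n$m >= 1) ||
    (n$s == 1 && n$m >= 1 && n$m <= 2) ||
    (n$s == 1 && n$p >= 2) ||
    n$m >= 3 ||
    (n$m == 2 && n$p >= 2) ||
    (n$m == 1 && n$p >= 4)
  benign <- n$ba >= 1 || n$bs >= 2
  likely_benign <- (n$bs == 1 && n$bp >= 1) || n$bp >= 2

  path_side <- pathogenic || likely_pathogenic
  benign_side <- benign || likely_benign
  if (path_side && benign_side) return("VUS")
  if (pathogenic) return("Pathogenic")
  if (likely_pathogenic) return("LikelyPathogenic")
  if (benign) return("Benign")
  if (likely_benign) return("LikelyBenign")
  "VUS"
}
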