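.complement <- c(A = "T", C = "G", G = "C", T = "A")

.comp_allele <- function(allele) {
  chars <- strsplit(allele, "", fixed = TRUE)
  vapply(chars, function(ch) {
    if (all(ch %in% names(.complement))) {
      paste(rev(unname(.complement[ch])), collapse = "")
    } else {
      NA_character_
    }
  }, character(1))
}

.is_palindromic <- function(ref, alt) {
  comp <- .comp_allele(alt)
  !is.na(comp) & ref == comp
}

#' Reconcile scoring-file alleles with VCF alleles
#'
#' Matches each scoring-file record against the cohort's variant list at the
#' same (chrom, pos) locus. A record matches "direct" when its effect allele
#' is the VCF ALT (and its other allele, if given, is REF), and "flipped"
#' when effect == REF and other == ALT (dosage then counts the reference
#' allele, 2 - alt_count). For non-palindromic allele pairs a
#' strand-complement match is also attempted; palindromic pairs (A/T, C/G)
#' are ambiguous under strand flips and match only in exact orientation.
#'
#' @param score_records Tibble from [parse_scorefile()].
#' @param vcf_variants Tibble with columns `chrom`, `pos`, `ref`, `alt`.
#' @return Tibble with one row per matched record: scoring columns plus
#'   `vcf_row` (row index into `vcf_variants`) and `orientation`
#'   ("direct"/"flipped"). Unmatched records are absent (they are a value,
#'   not an error).
#' @export
match_alleles <- function(score_records, vcf_variants) {
  locus_key <- paste(norm_chrom(vcf_variants$chrom), vcf_variants$pos)
  rec_key <- paste(norm_chrom(score_records$chrom), score_records$pos)

  out <- vector("list", nrow(score_records))
  for (i in seq_len(nrow(score_records))) {
    rows <- which(locus_key == rec_key[i])
    if (length(rows) == 0L) next
    ea <- score_records$effect_allele[i]
    oa <- score_records$other_allele[i]
    hit <- NA_integer_
    orientation <- NA_character_
    for (r in rows) {
      ref <- vcf_variants$ref[r]
      alt <- vcf_variants$alt[r]
      if (ea == alt && (is.na(oa) || oa == ref)) {
        hit <- r; orientation <- "direct"; break
      }
      if (!is.na(oa) && ea == ref && oa == alt) {
        hit <- r; orientation <- "flipped"; break
      }
      # strand-complement rescue, non-palindromic sites only
      if (!.is_palindromic(ref, alt)) {
        cea <- .comp_allele(ea)
        coa <- .comp_allele(oa)
        if (!is.na(cea) && cea == alt && (is.na(oa) || (!is.na(coa) && coa == ref))) {
          hit <- r; orientation <- "direct"; break
        }
        if (!is.na(oa) && !is.na(cea) && !is.na(coa) && cea == ref && coa == alt) {
          hit <- r; orientation <- "flipped"; break
        }
      }
    }
    if (!is.na(hit)) {
      out[[i]] <- tibble::tibble(score_row = i, vcf_row = hit,
                                 orientation = orientation)
    }
  }
  matched <- dplyr::bind_rows(out)
  if (nrow(matched) == 0L) {
    return(tibble::tibble(score_row = integer(0), vcf_row = integer(0),
                          orientation = character(0),
                          effect_weight = numeric(0)))
  }
  matched$effect_weight <- score_records$effect_weight[matched$score_row]
  matched
}

# effect-allele frequency per matched record, estimated from a cohort's
# non-missing dosages (used for mean imputation of missing genotypes)
effect_allele_freq <- function(matched, genotypes) {
  vapply(seq_len(nrow(matched)), function(i) {
    counts <- genotypes$alt_counts[matched$vcf_row[i], ]
    if (matched$orientation[i] == "flipped") counts <- 2L - counts
    mean(counts, na.rm = TRUE) / 2
  }, numeric(1))
}

#' Compute raw polygenic scores for every sample
#'
#' For each sample the score is the sum over matched scoring-file variants
#' of effect_weight x effect-allele dosage, where dosage = alt_count for a
#' direct match and 2 - alt_count for a flipped match. A missing genotype is
#' mean-imputed as 2 x effect-allele frequency taken from the reference
#' cohort. Score variants absent from the VCF contribute 0 and lower
#' `matched_fraction`.
#'
#' @param score_records Tibble from [parse_scorefile()].
#' @param genotypes A [genotype_matrix()] for the cohort to score.
#' @param reference_freqs Optional numeric vector of effect-allele
#'   frequencies, one per matched record (aligned with the rows of
#'   `matched`); when NULL, frequencies are estimated from `genotypes`
#'   itself.
#' @param matched Optional pre-computed [match_alleles()] result (used to
#'   score patients and controls on an identical matched set).
#' @param score_name Label stored in the result.
#' @param min_matched_fraction Warn when the matched fraction falls below
#'   this floor (default 0.9); error when nothing matches.
#' @return Tibble: sample, score_name, score, matched_fraction.
#' @export
compute_prs <- function(score_records, genotypes, reference_freqs = NULL,
                        matched = NULL, score_name = "score",
                        min_matched_fraction = 0.9) {
  if (is.null(matched)) {
    matched <- match_alleles(score_records, genotypes$variants)
  }
  n_rec <- nrow(score_records)
  frac <- nrow(matched) / n_rec
  if (nrow(matched) == 0L) {
    abort_fh("no scoring-file variant matched the VCF", "fh_prs_error")
  }
  if (frac < min_matched_fraction) {
    rlang::warn(sprintf(
      "only %.1f%% of scoring-file variants matched the VCF (floor %.1f%%)",
      100 * frac, 100 * min_matched_fraction))
  }
  if (is.null(reference_freqs)) {
    reference_freqs <- effect_allele_freq(matched, genotypes)
  }
  stopifnot(length(reference_freqs) == nrow(matched))

  dosage <- genotypes$alt_counts[matched$vcf_row, , drop = FALSE]
  flip <- matched$orientation == "flipped"
  dosage[flip, ] <- 2L - dosage[flip, , drop = FALSE]
  storage.mode(dosage) <- "double"
  for (i in which(rowSums(is.na(dosage)) > 0)) {
    dosage[i, is.na(dosage[i, ])] <- 2 * reference_freqs[i]
  }
  scores <- as.numeric(crossprod(dosage, matched$effect_weight))
  tibble::tibble(sample = genotypes$samples, score_name = score_name,
                 score = scores, matched_fraction = frac)
}

#' Build a reference score distribution from a control cohort
#'
#' Percentile cut points are nearest-rank order statistics of the sorted
#' control scores: the value at index ceiling(q x n), 1-based. At least 20
#' controls are required for the P95 cut to be meaningful.
#'
#' @param scores Numeric vector of control-cohort scores.
#' @return A `prs_reference` list: sorted `values`, `n`, and `cut_points`
#'   (P5, P25, P50, P75, P95).
#' @export
build_reference <- function(scores) {
  scores <- scores[!is.na(scores)]
  n <- length(scores)
  if (n < 20L) {
    abort_fh(paste0("reference cohort too small (n = ", n,
                    "; at least 20 required for P95 use)"), "fh_prs_error")
  }
  values <- sort(scores)
  qs <- c(P5 = 0.05, P25 = 0.25, P50 = 0.50, P75 = 0.75, P95 = 0.95)
  structure(list(values = values, n = n,
                 cut_points = vapply(qs, function(q) nearest_rank(values, q),
                                     numeric(1))),
            class = "prs_reference")
}

#' @export
print.prs_reference <- function(x, ...) {
  cat("<prs_reference> n =", x$n, "\n")
  print(x$cut_points)
  invisible(x)
}

#' Annotate scores with reference percentiles, P95 flag and quartile
#'
#' Percentile = 100 x (number of reference values strictly below the
#' score) / n. The high-PRS flag is strict: score > P95 cut value, so a
#' score tying the cut is not high. Quartiles follow the reference cuts:
#' Q1 < P25; Q2 in \[P25, P50); Q3 in \[P50, P75); Q4 >= P75. The low-PRS
#' flag is symmetric: score < P5 cut value.
#'
#' @param results Tibble from [compute_prs()].
#' @param reference A [build_reference()] object.
#' @return `results` with columns `percentile`, `high_prs`, `low_prs`,
#'   `quartile` appended.
#' @export
annotate_percentiles <- function(results, reference) {
  stopifnot(inherits(reference, "prs_reference"))
  cp <- reference$cut_points
  results$percentile <- vapply(results$score, function(s) {
    100 * sum(reference$values < s) / reference$n
  }, numeric(1))
  results$high_prs <- results$score > cp[["P95"]]
  results$low_prs <- results$score < cp[["P5"]]
  results$quartile <- dplyr::case_when(
    results$score < cp[["P25"]] ~ "Q1",
    results$score < cp[["P50"]] ~ "Q2",
    results$score < cp[["P75"]] ~ "Q3",
    TRUE ~ "Q4"
  )
  results
}

#' Score patients and controls on an identical matched-variant set
#'
#' Matches the scoring file against both cohorts, keeps only variants
#' matched in both (so scores are comparable), estimates effect-allele
#' frequencies from the controls, computes both cohorts' scores, builds the
#' control reference and annotates the patients.
#'
#' @param score_records Tibble from [parse_scorefile()].
#' @param patients,controls [genotype_matrix()] objects.
#' @param score_name Label for the score.
#' @param min_matched_fraction Passed to [compute_prs()].
#' @return List with `patients` (annotated tibble), `controls` (annotated
#'   tibble) and `reference` (the control distribution).
#' @export
score_cohorts <- function(score_records, patients, controls,
                          score_name = "score", min_matched_fraction = 0.9) {
  mp <- match_alleles(score_records, patients$variants)
  mc <- match_alleles(score_records, controls$variants)
  shared <- intersect(mp$score_row, mc$score_row)
  mp <- mp[mp$score_row %in% shared, , drop = FALSE]
  mc <- mc[mc$score_row %in% shared, , drop = FALSE]
  mp <- mp[order(mp$score_row), ]
  mc <- mc[order(mc$score_row), ]
  freqs <- effect_allele_freq(mc, controls)
  ctrl <- compute_prs(score_records, controls, reference_freqs = freqs,
                      matched = mc, score_name = score_name,
                      min_matched_fraction = min_matched_fraction)
  pat <- compute_prs(score_records, patients, reference_freqs = freqs,
                     matched = mp, score_name = score_name,
                     min_matched_fraction = min_matched_fraction)
  reference <- build_reference(ctrl$score)
  list(patients = annotate_percentiles(pat, reference),
       controls = annotate_percentiles(ctrl, reference),
       reference = reference)
}
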