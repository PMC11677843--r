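#' Normalize a chromosome label
#'
#' Chromosome labels are compared after stripping an optional "chr" prefix,
#' so mixed dialects ("chr19" vs "19") join correctly.
#'
#' @param chrom Character vector of chromosome labels.
#' @return Character vector without the "chr" prefix.
#' @export
norm_chrom <- function(chrom) {
  sub("^chr", "", as.character(chrom), ignore.case = TRUE)
}

# canonical string key for a (chrom, pos, ref, alt) variant; 1-based VCF coords
variant_id <- function(chrom, pos, ref, alt) {
  paste(norm_chrom(chrom), pos, ref, alt, sep = ":")
}

#' Round half away from zero
#'
#' Printed percentages in the cohort summaries use commercial rounding
#' (43.66 -> 43.7), not banker's rounding as in [base::round()].
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# nearest-rank (ceiling) empirical quantile: value at the ceiling(q*n)-th
# order statistic, 1-based; deterministic across platforms
nearest_rank <- function(sorted_values, q) {
  n <- length(sorted_values)
  idx <- pmax(1L, as.integer(ceiling(q * n)))
  sorted_values[pmin(idx, n)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_fh <- function(msg, class) {
  rlang::abort(msg, class = c(class, "fhyield_error"))
}
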