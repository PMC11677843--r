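#' Assign each patient to a genetic group
#'
#' A patient carrying any P/LP variant in a classic FH gene is FH_PLP; else
#' any P/LP in a phenocopy gene makes them PHENOCOPY_PLP; else NON_FH.
#' FH takes precedence over phenocopy when both occur, and zygosity does
#' not affect grouping (a heterozygous phenocopy carrier still counts).
#'
#' @param plp_genes List (one element per patient) of character vectors of
#'   genes in which the patient carries P/LP variants (possibly empty).
#' @param panel A [gene_panel()].
#' @return Character vector of groups: "FH_PLP", "PHENOCOPY_PLP", "NON_FH".
#' @export
classify_patient <- function(plp_genes, panel = gene_panel()) {
  vapply(plp_genes, function(genes) {
    if (any(genes %in% panel$fh_genes)) return("FH_PLP")
    if (any(genes %in% panel$phenocopy_genes)) return("PHENOCOPY_PLP")
    "NON_FH"
  }, character(1))
}

.prs_category <- function(high_ldl, high_lpa) {
  dplyr::case_when(
    high_ldl & high_lpa ~ "both",
    high_ldl ~ "ldl_only",
    high_lpa ~ "lpa_only",
    TRUE ~ "none"
  )
}

#' Cross-tabulate genetic groups against high-PRS categories
#'
#' Builds the cohort summary: per group (FH_PLP / PHENOCOPY_PLP / NON_FH)
#' the number of index patients whose LDL-C PRS only, LPA PRS only, both or
#' neither exceed the reference P95, plus the genetically explained total.
#' A patient is explained when they carry a P/LP variant (either panel) or,
#' lacking one, when at least one PRS is high. Relatives (is_index = FALSE)
#' are excluded from every denominator.
#'
#' @param patients Tibble with columns `sample`, `group`, `high_ldl`,
#'   `high_lpa`, optionally `is_index` (default TRUE) and `n_vus`.
#' @return A `cohort_summary` list: `table` (group x category counts),
#'   `n`, `explained`, `explained_pct`.
#' @export
summarize_cohort <- function(patients) {
  required <- c("sample", "group", "high_ldl", "high_lpa")
  missing_cols <- setdiff(required, names(patients))
  if (length(missing_cols) > 0L) {
    abort_fh(paste0("patients table lacks column(s): ",
                    paste(missing_cols, collapse = ", ")), "fh_cohort_error")
  }
  if (anyNA(patients$high_ldl) || anyNA(patients$high_lpa)) {
    bad <- patients$sample[is.na(patients$high_ldl) | is.na(patients$high_lpa)]
    abort_fh(paste0("patient(s) missing a PRS result: ",
                    paste(bad, collapse = ", ")), "fh_cohort_error")
  }
  if ("is_index" %in% names(patients)) {
    patients <- patients[patients$is_index, , drop = FALSE]
  }
  groups <- c("FH_PLP", "PHENOCOPY_PLP", "NON_FH")
  categories <- c("ldl_only", "lpa_only", "both", "none")
  patients$category <- .prs_category(patients$high_ldl, patients$high_lpa)
  tab <- patients |>
    dplyr::count(
      group = factor(.data$group, levels = groups),
      category = factor(.data$category, levels = categories),
      .drop = FALSE
    ) |>
    tidyr::pivot_wider(names_from = "category", values_from = "n",
                       values_fill = 0L)
  tab$size <- tab$ldl_only + tab$lpa_only + tab$both + tab$none
  n <- nrow(patients)
  stopifnot(sum(tab$size) == n)  # groups partition the cohort
  explained <- sum(tab$size[tab$group != "NON_FH"]) +
    sum(tab[tab$group == "NON_FH", c("ldl_only", "lpa_only", "both")])
  structure(list(
    table = tab,
    n = n,
    explained = explained,
    explained_pct = round_half_up(100 * explained / n, 1)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary> n =", x$n, "\n")
  print(as.data.frame(x$table))
  cat("explained:", x$explained, sprintf("(%.1f%%)\n", x$explained_pct))
  invisible(x)
}

#' Diagnostic-yield percentages from a cohort summary
#'
#' @param summary A [summarize_cohort()] result.
#' @return Named list of percentages (one decimal, half away from zero):
#'   `monogenic_fh` — FH-gene P/LP carriers / cohort;
#'   `monogenic_total` — all P/LP carriers / cohort;
#'   `prs_of_non_monogenic` — non-monogenic patients with any high PRS /
#'   non-monogenic patients;
#'   `prs_of_all` — the same numerator over the whole cohort;
#'   `combined` — explained total / cohort.
#' @export
diagnostic_yield <- function(summary) {
  stopifnot(inherits(summary, "cohort_summary"))
  tab <- summary$table
  n <- summary$n
  if (n == 0L) abort_fh("empty cohort", "fh_cohort_error")
  n_fh <- tab$size[tab$group == "FH_PLP"]
  n_pheno <- tab$size[tab$group == "PHENOCOPY_PLP"]
  non_fh <- tab[tab$group == "NON_FH", ]
  n_non <- non_fh$size
  n_non_high <- non_fh$ldl_only + non_fh$lpa_only + non_fh$both
  if (n_non == 0L) {
    abort_fh("no non-monogenic patients: PRS-explained ratio undefined",
             "fh_cohort_error")
  }
  pct <- function(num, den) round_half_up(100 * num / den, 1)
  list(
    monogenic_fh = pct(n_fh, n),
    monogenic_total = pct(n_fh + n_pheno, n),
    prs_of_non_monogenic = pct(n_non_high, n_non),
    prs_of_all = pct(n_non_high, n),
    combined = pct(summary$explained, n)
  )
}

#' Rank-based AUC (Mann-Whitney)
#'
#' Probability that a randomly chosen score from group A exceeds one from
#' group B, with ties counted one half: U / (n_a x n_b), U computed from
#' midranks.
#'
#' @param a,b Numeric score vectors (cases and controls, say).
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L) {
    abort_fh("both groups must be nonempty for AUC", "fh_cohort_error")
  }
  r <- rank(c(a, b))  # midranks handle ties as 1/2
  u <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  u / (length(a) * length(b))
}

#' Chi-square homogeneity test over PRS quartiles
#'
#' Pearson chi-square (no continuity correction) on a groups x quartiles
#' count table, e.g. FH vs non-FH across Q1-Q4 (df = 3).
#'
#' @param counts Integer matrix (rows = groups, columns = quartiles).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
quartile_homogeneity <- function(counts) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort_fh("zero row or column sum in quartile table", "fh_cohort_error")
  }
  ct <- stats::chisq.test(counts, correct = FALSE)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}
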