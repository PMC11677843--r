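#' Identify carriers of P/LP variants in a genotype matrix
#'
#' @param gm A [genotype_matrix()].
#' @param plp_variants Tibble with `chrom`, `pos`, `ref`, `alt`, `gene` for
#'   triaged P/LP variants.
#' @return Tibble (sample, gene, key) with one row per carried P/LP variant
#'   (alt count >= 1; missing genotypes do not count as carriage).
#' @export
plp_carriers <- function(gm, plp_variants) {
  keys <- variant_id(plp_variants$chrom, plp_variants$pos,
                     plp_variants$ref, plp_variants$alt)
  rows <- match(keys, rownames(gm$alt_counts))
  out <- list()
  for (i in seq_along(rows)) {
    if (is.na(rows[i])) next
    counts <- gm$alt_counts[rows[i], ]
    hit <- which(!is.na(counts) & counts >= 1L)
    if (length(hit) > 0L) {
      out[[length(out) + 1L]] <- tibble::tibble(
        sample = gm$samples[hit], gene = plp_variants$gene[i], key = keys[i])
    }
  }
  dplyr::bind_rows(out)
}

#' Run the full characterization pipeline on one study
#'
#' Triage of the variant tables, dual polygenic scoring of patients against
#' controls, patient grouping and the cohort diagnostic-yield summary — the
#' complete analysis over the objects produced by [simulate_study()] (or
#' equivalently over real inputs read with the io functions).
#'
#' @param study A [simulate_study()] result.
#' @param panel A [gene_panel()].
#' @return List: `triage` (per-variant calls), `prs` (named list of
#'   [score_cohorts()] results), `patients` (per-patient table with group
#'   and PRS flags), `summary` ([summarize_cohort()]), `yield`
#'   ([diagnostic_yield()]).
#' @export
run_pipeline <- function(study, panel = gene_panel()) {
  joined <- read_tables(study$tables$annotation, study$tables$clinvar,
                        study$tables$evidence)
  triage <- triage_variants(joined, panel = panel)
  plp <- triage[triage$is_plp, c("chrom", "pos", "ref", "alt", "gene")]

  prs <- lapply(names(study$scorefiles), function(nm) {
    score_cohorts(study$scorefiles[[nm]]$records, study$cohorts$patients,
                  study$cohorts$controls, score_name = nm)
  })
  names(prs) <- names(study$scorefiles)

  carriers <- plp_carriers(study$cohorts$patients, plp)
  genes_by_sample <- split(carriers$gene, carriers$sample)
  samples <- study$cohorts$patients$samples
  plp_genes <- lapply(samples, function(s) genes_by_sample[[s]] %||% character(0))

  patients <- tibble::tibble(
    sample = samples,
    group = classify_patient(plp_genes, panel),
    high_ldl = prs$ldl$patients$high_prs[match(samples, prs$ldl$patients$sample)],
    high_lpa = prs$lpa$patients$high_prs[match(samples, prs$lpa$patients$sample)],
    is_index = TRUE
  )
  summary <- summarize_cohort(patients)
  list(triage = triage, prs = prs, patients = patients, summary = summary,
       yield = diagnostic_yield(summary))
}
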