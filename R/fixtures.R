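#' Published P/LP variant list for the Latvian FH cohort
#'
#' Machine-readable transcription of the published table of the 43 unique
#' pathogenic / likely pathogenic variants (gene, HGVS label, rsID, ClinVar
#' accession and star level, zygosity, consequence, classification, carrier
#' count, plus flags for variants classified via the ACMG/AMP route, for
#' relatives among the carriers, and for the one compound-heterozygous
#' pair).
#'
#' @return Tibble with 43 rows.
#' @export
fh_table2 <- function() {
  path <- system.file("extdata", "table2_variants.tsv", package = "fhyield",
                      mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  na = "NA")
}

#' Published group-by-high-PRS cross-tabulation
#'
#' Transcription of the published summary counts: for each genetic group
#' (FH-gene P/LP carriers, phenocopy-gene P/LP carriers, patients without
#' P/LP) the number of index patients whose LDL-C PRS only, LPA PRS only,
#' both, or neither exceed the control-cohort P95, with the VUS counts per
#' cell.
#'
#' @return Tibble with columns group, category, n, vus_n.
#' @export
fh_table3 <- function() {
  path <- system.file("extdata", "table3_counts.tsv", package = "fhyield",
                      mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

# synthetic chromosome per gene, loosely matching real assignments
.gene_chrom <- c(LDLR = "19", APOB = "2", PCSK9 = "1", LDLRAP1 = "1",
                 ABCG5 = "2", ABCG8 = "2", APOE = "19", CYP27A1 = "2",
                 LIPA = "10", LPA = "6")

# ACMG evidence recipe consistent with a printed class and consequence;
# the published table reports outcomes only, not per-variant criteria
.evidence_recipe <- function(classification, consequence) {
  truncating <- consequence %in% c("stop gained", "frameshift")
  if (classification == "P") {
    if (truncating) "PVS1,PM2,PP1" else "PS3,PM1,PM2,PM5"
  } else if (consequence == "splice site") {
    "PVS1_Strong,PM2"  # conservative splice handling: PVS1 applied at Strong
  } else {
    "PM1,PM2,PP2,PP3"
  }
}

#' Build triage input tables from the published variant list
#'
#' The published table reports neither genomic coordinates, submitter
#' counts, gnomAD frequencies nor per-variant ACMG criteria. This helper
#' synthesizes those fields deterministically, consistent with what is
#' printed: ClinVar-trusted rows get enough submitters to pass the
#' star/submitter trust rule at their printed star level; rows flagged as
#' ACMG-classified get an evidence set whose combination reproduces the
#' printed class (splice-site variants via PVS1 applied at Strong); novel
#' variants get a missing PopMax FAF. Coordinates are synthetic placeholder
#' positions (unique per variant, chromosome chosen by gene).
#'
#' @return List of tibbles `annotation`, `clinvar`, `evidence` (ready for
#'   [read_tables()]), plus the transcription in `table2`.
#' @export
fixture_bundle <- function() {
  t2 <- fh_table2()
  n <- nrow(t2)
  chrom <- unname(.gene_chrom[t2$gene])
  pos <- 1000000L + seq_len(n) * 1000L
  ref <- rep("G", n)
  alt <- rep("A", n)

  annotation <- tibble::tibble(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    gene = t2$gene, consequence = t2$consequence,
    # novel variants are absent from gnomAD; known ones are very rare
    popmax_faf = ifelse(is.na(t2$rsid) & is.na(t2$clinvar_id), NA, 1e-4),
    rsid = t2$rsid
  )

  class_map <- c(P = "Pathogenic", LP = "Likely pathogenic",
                 `P/LP` = "Pathogenic/Likely pathogenic")
  in_clinvar <- !is.na(t2$clinvar_id)
  trusted <- in_clinvar & !t2$acmg_rule
  # 2-star trust needs >= 5 submitters; untrusted records get too few
  submitters <- ifelse(trusted & t2$gold_stars == 2, 6L,
                       ifelse(trusted, 2L, 3L))
  clinvar <- tibble::tibble(
    chrom = chrom[in_clinvar], pos = pos[in_clinvar],
    ref = ref[in_clinvar], alt = alt[in_clinvar],
    classification = unname(class_map[t2$classification[in_clinvar]]),
    gold_stars = as.integer(t2$gold_stars[in_clinvar]),
    submitter_count = submitters[in_clinvar],
    clinvar_id = as.character(t2$clinvar_id[in_clinvar])
  )

  acmg <- t2$acmg_rule
  evidence <- tibble::tibble(
    chrom = chrom[acmg], pos = pos[acmg], ref = ref[acmg], alt = alt[acmg],
    criteria = mapply(.evidence_recipe, t2$classification[acmg],
                      t2$consequence[acmg], USE.NAMES = FALSE)
  )

  list(annotation = annotation, clinvar = clinvar, evidence = evidence,
       table2 = t2)
}

#' Unique index carriers implied by the published variant list
#'
#' The carrier-count column counts each variant's carriers, so the
#' patient-level total must subtract the sequenced relatives and the second
#' listing of the one compound-heterozygous index patient.
#'
#' @param t2 Tibble from [fh_table2()].
#' @return List: `total_cases` (raw case-column sum), `index_carriers`,
#'   `fh_gene_carriers`, `phenocopy_carriers`.
#' @export
fixture_carriers <- function(t2 = fh_table2()) {
  panel <- gene_panel()
  n_rel <- sum(t2$n_relatives)
  # a compound-het pair shares one patient; both rows count the index once
  n_ch_extra <- sum(!is.na(t2$compound_het_partner)) / 2
  is_fh <- t2$gene %in% panel$fh_genes
  total <- sum(t2$cases)
  fh_carriers <- sum(t2$cases[is_fh]) - n_rel - n_ch_extra
  pheno_carriers <- sum(t2$cases[!is_fh])
  list(total_cases = total,
       index_carriers = total - n_rel - n_ch_extra,
       fh_gene_carriers = fh_carriers,
       phenocopy_carriers = pheno_carriers)
}

#' Expand the published cross-tabulation into patient-level rows
#'
#' Rehydrates one row per index patient from the published counts so the
#' cohort summary path can be exercised end to end on the published data.
#'
#' @param t3 Tibble from [fh_table3()].
#' @return Patients tibble suitable for [summarize_cohort()].
#' @export
expand_table3 <- function(t3 = fh_table3()) {
  rows <- t3[rep(seq_len(nrow(t3)), t3$n), ]
  tibble::tibble(
    sample = sprintf("PT%03d", seq_len(nrow(rows))),
    group = rows$group,
    high_ldl = rows$category %in% c("ldl_only", "both"),
    high_lpa = rows$category %in% c("lpa_only", "both"),
    is_index = TRUE
  )
}
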