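#' Configuration for the synthetic study generator
#'
#' Defaults emulate the study conditions of the cohort the pipeline was
#' built around: 339 index patients against 515 population controls, an
#' LDL-C score of 500 loci and an Lp(a) score of 40 loci, 73/339 patients
#' carrying a planted FH-gene P/LP variant and 7/339 a phenocopy-gene one,
#' and a standardized polygenic liability shift of the non-monogenic
#' patients calibrated so that the expected patient-vs-control rank AUC is
#' 0.711 for the LDL-C score (delta = sqrt(2) * qnorm(AUC)) and 0.558 for
#' the Lp(a) score.
#'
#' @param n_patients,n_controls Cohort sizes.
#' @param n_score_loci Named integer vector of loci per score.
#' @param allele_freq_range Range the effect-allele frequencies are drawn
#'   from (uniform).
#' @param weight_scale Standard deviation of the Normal(0, sd) effect
#'   weights.
#' @param f_monogenic Fraction of patients given a planted heterozygous
#'   FH-gene P/LP variant.
#' @param f_phenocopy Fraction given a phenocopy-gene P/LP variant.
#' @param polygenic_shift Named vector of standardized mean score shifts
#'   (in control-cohort SD units) applied to non-monogenic patients.
#' @param missing_rate Per-genotype missingness probability at score loci.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 339L, n_controls = 515L,
                       n_score_loci = c(ldl = 500L, lpa = 40L),
                       allele_freq_range = c(0.05, 0.95),
                       weight_scale = 0.1,
                       f_monogenic = 73 / 339,
                       f_phenocopy = 7 / 339,
                       polygenic_shift = c(ldl = sqrt(2) * stats::qnorm(0.711),
                                           lpa = sqrt(2) * stats::qnorm(0.558)),
                       missing_rate = 0.002) {
  stopifnot(n_controls >= 20L, all(polygenic_shift >= 0),
            f_monogenic >= 0, f_monogenic <= 1,
            f_phenocopy >= 0, f_phenocopy <= 1,
            missing_rate >= 0, missing_rate < 1)
  structure(list(n_patients = as.integer(n_patients),
                 n_controls = as.integer(n_controls),
                 n_score_loci = n_score_loci,
                 allele_freq_range = allele_freq_range,
                 weight_scale = weight_scale,
                 f_monogenic = f_monogenic,
                 f_phenocopy = f_phenocopy,
                 polygenic_shift = polygenic_shift,
                 missing_rate = missing_rate),
            class = "sim_config")
}

.bases <- c("A", "C", "G", "T")

#' Generate a synthetic PGS-Catalog-style scoring file
#'
#' Draws distinct positions, random ref/alt pairs, Normal(0, weight_scale^2)
#' effect weights and uniform effect-allele frequencies. The effect allele
#' is assigned to ALT or REF at random so that downstream allele matching
#' exercises both direct and flipped orientations.
#'
#' @param config A [sim_config()].
#' @param score_name Which score to generate ("ldl" or "lpa", or any name
#'   present in `config$n_score_loci`).
#' @param chrom Chromosome label for the score's loci.
#' @return List: `records` (a [parse_scorefile()]-shaped tibble), `loci`
#'   (records plus the VCF-side `ref`/`alt` alleles and the true ALT-allele
#'   frequency `alt_freq`).
#' @export
generate_scorefile <- function(config, score_name = "ldl", chrom = "1") {
  n <- config$n_score_loci[[score_name]]
  pos <- sort(sample.int(5e7, n))
  ref <- sample(.bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(.bases, r), 1), character(1))
  weight <- stats::rnorm(n, 0, config$weight_scale)
  alt_freq <- stats::runif(n, config$allele_freq_range[1],
                           config$allele_freq_range[2])
  effect_is_alt <- sample(c(TRUE, FALSE), n, replace = TRUE)
  records <- tibble::tibble(
    variant_id = sprintf("rs%s%06d", score_name, seq_len(n)),
    chrom = chrom,
    pos = pos,
    effect_allele = ifelse(effect_is_alt, alt, ref),
    other_allele = ifelse(effect_is_alt, ref, alt),
    effect_weight = weight
  )
  loci <- dplyr::mutate(records, ref = ref, alt = alt, alt_freq = alt_freq,
                        effect_is_alt = effect_is_alt,
                        score_name = score_name)
  list(records = records, loci = loci)
}

# exponential-tilt (first order) of ALT-allele frequencies so that the
# expected score of a tilted genome exceeds the control mean by
# delta control-SDs; errors when the tilt leaves the unit interval
.tilted_freqs <- function(loci, delta) {
  w_alt <- ifelse(loci$effect_is_alt, loci$effect_weight, -loci$effect_weight)
  p <- loci$alt_freq
  v <- sum(w_alt^2 * 2 * p * (1 - p))
  if (v <= 0 && delta > 0) {
    abort_fh("score has zero variance; polygenic shift unreachable",
             "fh_sim_error")
  }
  if (delta == 0) return(p)
  eps <- delta / sqrt(v)
  p_tilt <- p + eps * w_alt * p * (1 - p)
  if (any(p_tilt <= 0 | p_tilt >= 1)) {
    abort_fh(paste0("polygenic shift ", signif(delta, 3),
                    " unreachable with these weights; ",
                    "increase n_score_loci"), "fh_sim_error")
  }
  p_tilt
}

.draw_genotypes <- function(freqs, n_samples) {
  matrix(stats::rbinom(length(freqs) * n_samples, 2L,
                       rep(freqs, n_samples)),
         nrow = length(freqs))
}

#' Generate patient and control genotype cohorts
#'
#' Controls are drawn under Hardy-Weinberg from the scorefile truth
#' frequencies. Patients are split into monogenic carriers (genotypes drawn
#' like controls, plus one planted heterozygous P/LP variant each) and
#' non-monogenic patients, whose score-locus allele frequencies are tilted
#' so their expected standardized score sits `polygenic_shift` control-SDs
#' above the control mean. Missingness is applied uniformly at the score
#' loci.
#'
#' @param config A [sim_config()].
#' @param score_defs List of [generate_scorefile()] outputs (one per score).
#' @param plp_variants Tibble of plantable P/LP variants with columns
#'   `chrom`, `pos`, `ref`, `alt`, `gene` (FH and/or phenocopy genes).
#' @return List: `patients` and `controls` ([genotype_matrix()]s), `truth`
#'   (per-patient tibble: sample, monogenic, planted_gene, planted_key,
#'   ldl_c phenotype), `loci` (combined locus truth table).
#' @export
generate_cohorts <- function(config, score_defs, plp_variants) {
  loci <- dplyr::bind_rows(lapply(score_defs, `[[`, "loci"))
  panel <- gene_panel()
  n_pat <- config$n_patients
  n_ctl <- config$n_controls

  samples_ctl <- sprintf("CTL%04d", seq_len(n_ctl))
  samples_pat <- sprintf("PAT%04d", seq_len(n_pat))

  ctl_counts <- .draw_genotypes(loci$alt_freq, n_ctl)

  # assign planted carriers
  n_mono <- round(config$f_monogenic * n_pat)
  n_pheno <- round(config$f_phenocopy * n_pat)
  carriers <- sample(seq_len(n_pat), n_mono + n_pheno)
  mono_idx <- carriers[seq_len(n_mono)]
  pheno_idx <- setdiff(carriers, mono_idx)
  fh_pool <- plp_variants[plp_variants$gene %in% panel$fh_genes, , drop = FALSE]
  ph_pool <- plp_variants[plp_variants$gene %in% panel$phenocopy_genes, , drop = FALSE]
  if (n_mono > 0L && nrow(fh_pool) == 0L) {
    abort_fh("no FH-gene P/LP variants available to plant", "fh_sim_error")
  }
  if (n_pheno > 0L && nrow(ph_pool) == 0L) {
    abort_fh("no phenocopy-gene P/LP variants available to plant",
             "fh_sim_error")
  }
  planted <- rep(NA_integer_, n_pat)
  planted[mono_idx] <- sample(nrow(fh_pool), n_mono, replace = TRUE)
  planted[pheno_idx] <- nrow(fh_pool) +
    sample(nrow(ph_pool), n_pheno, replace = TRUE)
  pool <- dplyr::bind_rows(fh_pool, ph_pool)

  # score-locus genotypes: tilted for non-monogenic, control-like otherwise
  tilt <- lapply(score_defs, function(sd) {
    .tilted_freqs(sd$loci, config$polygenic_shift[[sd$loci$score_name[1]]])
  })
  freq_tilted <- unlist(tilt, use.names = FALSE)
  pat_counts <- matrix(0L, nrow = nrow(loci), ncol = n_pat)
  is_mono <- seq_len(n_pat) %in% carriers
  if (any(is_mono)) {
    pat_counts[, is_mono] <- .draw_genotypes(loci$alt_freq, sum(is_mono))
  }
  if (any(!is_mono)) {
    pat_counts[, !is_mono] <- .draw_genotypes(freq_tilted, sum(!is_mono))
  }

  # missingness at score loci only
  if (config$missing_rate > 0) {
    drop_ctl <- stats::runif(length(ctl_counts)) < config$missing_rate
    ctl_counts[drop_ctl] <- NA_integer_
    drop_pat <- stats::runif(length(pat_counts)) < config$missing_rate
    pat_counts[drop_pat] <- NA_integer_
  }

  # planted rare variants appended to the patient matrix (absent from
  # controls, which are only genotyped over the score intervals)
  plant_counts <- matrix(0L, nrow = nrow(pool), ncol = n_pat)
  for (i in which(!is.na(planted))) {
    plant_counts[planted[i], i] <- 1L
  }
  score_vars <- loci[, c("chrom", "pos", "ref", "alt")]
  patients <- genotype_matrix(
    dplyr::bind_rows(score_vars, pool[, c("chrom", "pos", "ref", "alt")]),
    rbind(pat_counts, plant_counts), samples_pat)
  controls <- genotype_matrix(score_vars, ctl_counts, samples_ctl)

  # documentation-realism phenotype, anchored to the published lipid means
  ldl_c <- ifelse(is_mono, stats::rnorm(n_pat, 8.3, 1.8),
                  stats::rnorm(n_pat, 6.8, 1.2))
  truth <- tibble::tibble(
    sample = samples_pat,
    monogenic = is_mono,
    planted_gene = ifelse(is.na(planted), NA_character_, pool$gene[planted]),
    planted_key = ifelse(is.na(planted), NA_character_,
                         variant_id(pool$chrom[planted], pool$pos[planted],
                                    pool$ref[planted], pool$alt[planted])),
    ldl_c = ldl_c
  )
  list(patients = patients, controls = controls, truth = truth, loci = loci)
}

# evidence-set templates spanning every combination-rule branch; expected
# class recorded alongside for coverage checks
.acmg_branch_templates <- function() {
  tibble::tribble(
    ~criteria, ~expected, ~branch,
    "PVS1,PS1", "Pathogenic", "vs+s",
    "PVS1,PM1,PM2", "Pathogenic", "vs+2m",
    "PVS1,PM1,PP1", "Pathogenic", "vs+m+p",
    "PVS1,PP1,PP2", "Pathogenic", "vs+2p",
    "PVS1,PS1_VeryStrong", "Pathogenic", "2vs",
    "PS1,PS2", "Pathogenic", "2s",
    "PS1,PM1,PM2,PM4", "Pathogenic", "s+3m",
    "PS1,PM1,PM2,PP1,PP2", "Pathogenic", "s+2m+2p",
    "PS1,PM1,PP1,PP2,PP3,PP4", "Pathogenic", "s+m+4p",
    "PVS1,PM1", "LikelyPathogenic", "vs+m",
    "PS1,PM1", "LikelyPathogenic", "s+1m",
    "PS1,PM1,PM2", "LikelyPathogenic", "s+2m",
    "PS1,PP1,PP2", "LikelyPathogenic", "s+2p",
    "PM1,PM2,PM4", "LikelyPathogenic", "3m",
    "PM1,PM2,PP1,PP2", "LikelyPathogenic", "2m+2p",
    "PM1,PP1,PP2,PP3,PP4", "LikelyPathogenic", "m+4p",
    "BA1", "Benign", "standalone",
    "BS1,BS2", "Benign", "2bs",
    "BS1,BP1", "LikelyBenign", "bs+bp",
    "BP1,BP2", "LikelyBenign", "2bp",
    "PS1,PS2,BA1", "VUS", "conflict",
    "PM1,PP1", "VUS", "no-rule"
  )
}

#' Generate annotation / ClinVar / evidence tables for the triage cascade
#'
#' Emits a deterministic mix of variants exercising every triage branch:
#' (a) common variants with PopMax FAF above the 0.5% filter; (b)
#' ClinVar-trusted P/LP records at both trust levels (2 stars with >= 5
#' submitters; >= 3 stars); (c) evidence sets spanning every ACMG
#' combination-rule branch; (d) VUS including promotable priority cases in
#' an FH gene and the same evidence in a non-FH gene.
#'
#' @param config A [sim_config()] (unused sizes are fine; kept for a stable
#'   signature).
#' @return List of tibbles: `annotation`, `clinvar`, `evidence`, and
#'   `truth` (expected triage class and category per variant).
#' @export
generate_variant_tables <- function(config = sim_config()) {
  templates <- .acmg_branch_templates()
  spec <- dplyr::bind_rows(
    tibble::tibble(category = "common", gene = "LDLR", criteria = "",
                   expected = "FrequencyFiltered",
                   classification = "absent", gold_stars = 0L,
                   submitter_count = 0L, popmax_faf = c(0.02, 0.006)),
    tibble::tibble(category = "clinvar_trusted", gene = c("LDLR", "APOB"),
                   criteria = "",
                   expected = c("Pathogenic", "PathogenicLikelyPathogenic"),
                   classification = c("Pathogenic",
                                      "Pathogenic/Likely pathogenic"),
                   gold_stars = c(3L, 2L), submitter_count = c(1L, 6L),
                   popmax_faf = 1e-4),
    tibble::tibble(category = "clinvar_untrusted", gene = "LDLR",
                   criteria = "PS1,PM1",
                   expected = "LikelyPathogenic",
                   classification = "Likely pathogenic", gold_stars = 2L,
                   submitter_count = 4L, popmax_faf = 1e-4),
    tibble::tibble(category = "acmg",
                   gene = rep_len(c("LDLR", "APOB", "PCSK9", "LIPA", "ABCG8"),
                                  nrow(templates)),
                   criteria = templates$criteria,
                   expected = templates$expected,
                   classification = "absent", gold_stars = 0L,
                   submitter_count = 0L, popmax_faf = NA_real_),
    tibble::tibble(category = "priority_vus",
                   gene = c("LDLR", "APOB"), criteria = c("PS4", "PM1,PM2"),
                   expected = "VUS", classification = "absent",
                   gold_stars = 0L, submitter_count = 0L,
                   popmax_faf = NA_real_),
    tibble::tibble(category = "nonpriority_vus",
                   gene = c("LDLR", "ABCG8"), criteria = c("PP3", "PS4"),
                   expected = "VUS", classification = "absent",
                   gold_stars = 0L, submitter_count = 0L,
                   popmax_faf = NA_real_)
  )
  n <- nrow(spec)
  spec$chrom <- "22"
  spec$pos <- 10000000L + seq_len(n) * 500L
  spec$ref <- "C"
  spec$alt <- "T"

  annotation <- tibble::tibble(
    chrom = spec$chrom, pos = spec$pos, ref = spec$ref, alt = spec$alt,
    gene = spec$gene, consequence = "missense",
    popmax_faf = spec$popmax_faf, rsid = NA_character_
  )
  has_cv <- spec$classification != "absent"
  clinvar <- tibble::tibble(
    chrom = spec$chrom[has_cv], pos = spec$pos[has_cv],
    ref = spec$ref[has_cv], alt = spec$alt[has_cv],
    classification = spec$classification[has_cv],
    gold_stars = spec$gold_stars[has_cv],
    submitter_count = spec$submitter_count[has_cv],
    clinvar_id = sprintf("CV%05d", which(has_cv))
  )
  has_ev <- nzchar(spec$criteria)
  evidence <- tibble::tibble(
    chrom = spec$chrom[has_ev], pos = spec$pos[has_ev],
    ref = spec$ref[has_ev], alt = spec$alt[has_ev],
    criteria = spec$criteria[has_ev]
  )
  truth <- tibble::tibble(
    key = variant_id(spec$chrom, spec$pos, spec$ref, spec$alt),
    chrom = spec$chrom, pos = spec$pos, ref = spec$ref, alt = spec$alt,
    gene = spec$gene, category = spec$category, expected = spec$expected
  )
  list(annotation = annotation, clinvar = clinvar, evidence = evidence,
       truth = truth)
}

#' Generate a complete synthetic study
#'
#' Wires the generators together: scoring files for both scores, triage
#' tables, and patient/control cohorts with monogenic variants planted from
#' the generated P/LP set. With `out_dir` set, writes every input in its
#' external format (VCFs, scoring files, TSVs).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the whole study is a deterministic function of
#'   (config, seed).
#' @param out_dir Optional output directory.
#' @return List: `scorefiles` (per-score generator outputs), `tables`,
#'   `cohorts`, `config`, `seed`.
#' @export
simulate_study <- function(config = sim_config(), seed = 1L, out_dir = NULL) {
  set.seed(seed)
  score_chroms <- c(ldl = "1", lpa = "6")
  scorefiles <- lapply(names(config$n_score_loci), function(nm) {
    generate_scorefile(config, nm, chrom = score_chroms[[nm]] %||% "1")
  })
  names(scorefiles) <- names(config$n_score_loci)
  tables <- generate_variant_tables(config)
  plp <- tables$truth[tables$truth$expected %in%
                        c("Pathogenic", "LikelyPathogenic",
                          "PathogenicLikelyPathogenic"), ]
  cohorts <- generate_cohorts(config, scorefiles, plp)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_genotypes_vcf(cohorts$patients, file.path(out_dir, "patients.vcf"))
    write_genotypes_vcf(cohorts$controls, file.path(out_dir, "controls.vcf"))
    for (nm in names(scorefiles)) {
      write_scorefile(scorefiles[[nm]]$records,
                      file.path(out_dir, paste0("scorefile_", nm, ".txt")),
                      name = nm)
    }
    readr::write_tsv(tables$annotation, file.path(out_dir, "annotation.tsv"))
    readr::write_tsv(tables$clinvar, file.path(out_dir, "clinvar.tsv"))
    readr::write_tsv(tables$evidence, file.path(out_dir, "evidence.tsv"))
    readr::write_tsv(cohorts$truth, file.path(out_dir, "truth.tsv"))
  }
  list(scorefiles = scorefiles, tables = tables, cohorts = cohorts,
       config = config, seed = seed)
}
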