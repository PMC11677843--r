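make_gm <- function(variants, counts, samples = sprintf("S%d", seq_len(ncol(counts)))) {
  genotype_matrix(variants, counts, samples)
}

test_that("allele matching handles direct, flipped, strand and palindromic cases", {
  site <- tibble::tibble(chrom = "1", pos = 100L, ref = "G", alt = "A")
  rec <- function(ea, oa) tibble::tibble(variant_id = "rs1", chrom = "1",
                                         pos = 100L, effect_allele = ea,
                                         other_allele = oa,
                                         effect_weight = 1)
  expect_equal(match_alleles(rec("A", "G"), site)$orientation, "direct")
  expect_equal(match_alleles(rec("G", "A"), site)$orientation, "flipped")
  # opposite strand, non-palindromic: T/C complements to A/G -> direct
  expect_equal(match_alleles(rec("T", "C"), site)$orientation, "direct")
  # different locus -> unmatched is a value, not an error
  expect_equal(nrow(match_alleles(rec("A", "G"),
                                  tibble::tibble(chrom = "1", pos = 999L,
                                                 ref = "G", alt = "A"))), 0L)
  # palindromic site T/A: opposite-strand record must NOT rescue
  pal <- tibble::tibble(chrom = "1", pos = 100L, ref = "T", alt = "A")
  expect_equal(nrow(match_alleles(rec("A", "T"), pal)), 1L)  # exact ok
  expect_equal(match_alleles(rec("A", "T"), pal)$orientation, "direct")
  rec_opp <- rec("T", "A")  # still an exact (flipped) configuration
  expect_equal(match_alleles(rec_opp, pal)$orientation, "flipped")
  # alleles that could only match via a strand flip stay unmatched at a
  # palindromic site...
  expect_equal(nrow(match_alleles(rec("C", "G"), pal)), 0L)
  # ...whereas the same complement rescue succeeds at a non-palindromic one
  site_ct <- tibble::tibble(chrom = "1", pos = 100L, ref = "C", alt = "T")
  expect_equal(match_alleles(rec("A", "G"), site_ct)$orientation, "direct")
})

test_that("scores are weight-times-dosage sums with mean imputation", {
  variants <- tibble::tibble(chrom = "1", pos = c(10L, 20L),
                             ref = c("G", "C"), alt = c("A", "T"))
  counts <- matrix(c(2L, 0L,   # S1
                     0L, NA), nrow = 2)
  gm <- make_gm(variants, counts, c("S1", "S2"))
  recs <- tibble::tibble(
    variant_id = c("rs1", "rs2"), chrom = "1", pos = c(10L, 20L),
    effect_allele = c("A", "C"), other_allele = c("G", "T"),
    effect_weight = c(0.3, 0.5))
  # rs1 direct; rs2 flipped (effect = ref C)
  matched <- match_alleles(recs, variants)
  res <- compute_prs(recs, gm, reference_freqs = c(0.5, 0.75),
                     matched = matched)
  # S1: 0.3*2 + 0.5*(2-0) = 1.6
  expect_equal(res$score[res$sample == "S1"], 1.6)
  # S2 rs2 missing: flipped effect freq 0.75 -> imputed dosage 1.5
  expect_equal(res$score[res$sample == "S2"], 0.3 * 0 + 0.5 * 1.5)
  expect_equal(res$matched_fraction, c(1, 1))

  # all-zero weights give all-zero scores
  recs0 <- dplyr::mutate(recs, effect_weight = 0)
  expect_equal(compute_prs(recs0, gm, c(0.5, 0.75),
                           match_alleles(recs0, variants))$score, c(0, 0))

  # unmatched scorefile rows lower the matched fraction and warn below floor
  far <- dplyr::bind_rows(recs, dplyr::mutate(recs, pos = pos + 1000L,
                                              variant_id = c("rs3", "rs4")))
  expect_warning(res2 <- compute_prs(far, gm, score_name = "s"),
                 "matched")
  expect_equal(unique(res2$matched_fraction), 0.5)
  none <- dplyr::mutate(recs, pos = pos + 9999L)
  expect_error(compute_prs(none, gm), class = "fh_prs_error")
})

test_that("reference cut points are nearest-rank order statistics", {
  ref <- build_reference(1:100)
  expect_equal(ref$cut_points[["P95"]], 95)
  expect_equal(ref$cut_points[["P25"]], 25)
  # nearest-rank P50 of ten values is the ceiling(5.0) = 5th order statistic
  expect_equal(fhyield:::nearest_rank(1:10, 0.5), 5)
  const <- build_reference(rep(7, 50))
  expect_true(all(const$cut_points == 7))
  expect_error(build_reference(1:19), class = "fh_prs_error")
})

test_that("percentile annotation uses strict inequality at P95", {
  ref <- build_reference(1:100)
  res <- tibble::tibble(sample = c("a", "b", "c"), score_name = "s",
                        score = c(95, 96, 0.5), matched_fraction = 1)
  ann <- annotate_percentiles(res, ref)
  expect_false(ann$high_prs[1])   # tie with P95 value is not high
  expect_true(ann$high_prs[2])    # 96 > 95
  expect_equal(ann$percentile[3], 0)
  expect_equal(ann$quartile, c("Q4", "Q4", "Q1"))
  expect_true(ann$low_prs[3])
})

test_that("quartiles partition any annotated cohort", {
  set.seed(5)
  ref <- build_reference(rnorm(200))
  res <- tibble::tibble(sample = sprintf("s%d", 1:150), score_name = "s",
                        score = rnorm(150), matched_fraction = 1)
  ann <- annotate_percentiles(res, ref)
  expect_equal(sum(table(factor(ann$quartile, c("Q1", "Q2", "Q3", "Q4")))),
               150L)
})

test_that("flipping every scorefile record leaves ranking quantities unchanged", {
  set.seed(31)
  cfg <- sim_config(n_patients = 40L, n_controls = 60L,
                    n_score_loci = c(ldl = 60L), polygenic_shift = c(ldl = 0.5),
                    missing_rate = 0.01)
  study <- simulate_study(cfg, seed = 31L)
  recs <- study$scorefiles$ldl$records
  flipped <- dplyr::mutate(recs,
                           effect_allele = recs$other_allele,
                           other_allele = recs$effect_allele,
                           effect_weight = -recs$effect_weight)
  a <- score_cohorts(recs, study$cohorts$patients, study$cohorts$controls)
  b <- score_cohorts(flipped, study$cohorts$patients, study$cohorts$controls)
  # scores shift by a per-cohort constant; ranking quantities are invariant
  shift <- b$patients$score - a$patients$score
  expect_lt(diff(range(shift)), 1e-9)
  expect_equal(b$patients$percentile, a$patients$percentile)
  expect_equal(b$patients$high_prs, a$patients$high_prs)
  expect_equal(b$patients$quartile, a$patients$quartile)
})

test_that("about 5% of held-out same-distribution samples flag as high PRS", {
  set.seed(77)
  cfg <- sim_config(n_controls = 2000L, n_score_loci = c(ldl = 150L),
                    polygenic_shift = c(ldl = 0), missing_rate = 0)
  def <- generate_scorefile(cfg, "ldl")
  draw <- function(n) {
    counts <- matrix(stats::rbinom(nrow(def$loci) * n, 2L,
                                   rep(def$loci$alt_freq, n)),
                     nrow = nrow(def$loci))
    genotype_matrix(def$loci[, c("chrom", "pos", "ref", "alt")], counts,
                    sprintf("S%04d", seq_len(n)))
  }
  ref_scores <- compute_prs(def$records, draw(2000L))$score
  ref <- build_reference(ref_scores)
  held_out <- annotate_percentiles(compute_prs(def$records, draw(2000L)), ref)
  expect_gte(mean(held_out$high_prs), 0.03)
  expect_lte(mean(held_out$high_prs), 0.07)
})
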