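test_that("frequency filter is strict at the threshold and keeps missing FAF", {
  expect_false(filter_by_faf(0.006))        # above 0.5% -> discard
  expect_true(filter_by_faf(0.005))         # boundary retained
  expect_true(filter_by_faf(NA))            # novel variant retained
  expect_error(filter_by_faf(1.2), class = "fh_triage_error")
  # threshold extremes
  expect_true(all(filter_by_faf(c(0.1, 0.99, NA), threshold = 1)))
  faf <- c(1e-6, 0.4, NA)
  expect_equal(filter_by_faf(faf, threshold = 1e-9), c(FALSE, FALSE, TRUE))
})

test_that("ClinVar trust rule needs P/LP plus stars/submitters", {
  expect_equal(classify_by_clinvar("Pathogenic", 3L, 1L), "Pathogenic")
  expect_equal(classify_by_clinvar("Likely pathogenic", 2L, 5L),
               "LikelyPathogenic")
  expect_equal(classify_by_clinvar("Pathogenic/Likely pathogenic", 4L, 9L),
               "PathogenicLikelyPathogenic")
  expect_true(is.na(classify_by_clinvar("Pathogenic", 2L, 4L)))  # both rules fail
  expect_true(is.na(classify_by_clinvar("VUS", 4L, 20L)))        # not P/LP
  expect_true(is.na(classify_by_clinvar("Conflicting", 3L, 8L)))
  expect_true(is.na(classify_by_clinvar("absent", 0L, 0L)))
})

test_that("evidence combination reproduces the worked classifications", {
  expect_equal(combine_acmg(parse_criteria("PVS1,PS3")), "Pathogenic")
  expect_equal(combine_acmg(parse_criteria("")), "VUS")
  # splice variant handled conservatively: PVS1 applied at Strong + PM2
  expect_equal(combine_acmg(parse_criteria("PVS1_Strong,PM2")),
               "LikelyPathogenic")
  expect_equal(combine_acmg(parse_criteria("PM1,PM2,PP3")), "VUS")
  expect_equal(combine_acmg(parse_criteria("BA1")), "Benign")
  expect_equal(combine_acmg(parse_criteria("BS1,BP4")), "LikelyBenign")
  expect_equal(combine_acmg(parse_criteria("PS3,PS4,BA1")), "VUS")  # conflict
  expect_error(parse_criteria("QQ1"), class = "fh_acmg_error")
  expect_error(acmg_evidence("PM1", "Middling"), class = "fh_acmg_error")
  expect_error(acmg_evidence(c("PM1", "PM1"), c("Moderate", "Moderate")),
               class = "fh_acmg_error")
})

test_that("combiner agrees with the enumerated rule-table oracle", {
  tallies <- all_evidence_tallies(4L)  # 330 tallies; full sweep in acceptance
  for (i in seq_len(nrow(tallies))) {
    t <- tallies[i, ]
    got <- combine_acmg(evidence_from_tally(t$vs, t$s, t$m, t$p,
                                            t$ba, t$bs, t$bp))
    want <- oracle_acmg(t$vs, t$s, t$m, t$p, t$ba, t$bs, t$bp)
    if (!identical(got, want)) {
      fail(sprintf("tally (%s) -> %s, oracle %s",
                   paste(unlist(t), collapse = ","), got, want))
    }
  }
  succeed()
})

test_that("adding pathogenic evidence never demotes a classification", {
  set.seed(202)
  strengths <- c("VeryStrong", "Strong", "Moderate", "Supporting",
                 "StandAloneBenign", "BenignStrong", "BenignSupporting")
  for (rep in 1:200) {
    k <- sample(0:5, 1)
    base <- sample(strengths, k, replace = TRUE)
    ev <- acmg_evidence(sprintf("X%d", seq_len(k)), base)
    before <- combine_acmg(ev)
    add <- sample(c("VeryStrong", "Strong", "Moderate", "Supporting"), 1)
    after <- combine_acmg(acmg_evidence(sprintf("X%d", seq_len(k + 1)),
                                        c(base, add)))
    ok <- class_rank(after) >= class_rank(before) || after == "VUS"
    if (!ok) {
      fail(sprintf("{%s} + %s moved %s -> %s",
                   paste(base, collapse = ","), add, before, after))
    }
  }
  succeed()
})

test_that("the cascade filters before trusting ClinVar", {
  res <- classify_variant(popmax_faf = 0.02, classification = "Pathogenic",
                          gold_stars = 3L, submitter_count = 9L)
  expect_equal(res$class, "FrequencyFiltered")
  expect_equal(res$source, "FrequencyFiltered")

  res <- classify_variant(popmax_faf = NA, classification = "absent",
                          criteria = "")
  expect_equal(res$class, "VUS")
  expect_equal(res$source, "AcmgCombination")

  res <- classify_variant(popmax_faf = 1e-4,
                          classification = "Likely pathogenic",
                          gold_stars = 2L, submitter_count = 2L,
                          criteria = "PS1,PM1")
  expect_equal(res$source, "AcmgCombination")  # trust failed, fell through
  expect_equal(res$class, "LikelyPathogenic")
})

test_that("published variant list triages to 43 P/LP calls", {
  b <- fixture_bundle()
  tr <- triage_variants(read_tables(b$annotation, b$clinvar, b$evidence))
  expect_equal(nrow(tr), 43L)
  expect_true(all(tr$is_plp))
  expect_equal(sum(tr$gene %in% gene_panel()$fh_genes), 39L)
  expect_equal(sum(tr$source == "AcmgCombination"), sum(b$table2$acmg_rule))
  # printed class reproduced row by row
  want <- c(P = "Pathogenic", LP = "LikelyPathogenic",
            `P/LP` = "PathogenicLikelyPathogenic")[b$table2$classification]
  expect_equal(tr$class, unname(want))
})

test_that("priority VUS are one Moderate or Supporting short of LP, FH genes only", {
  panel <- gene_panel()
  # one Strong: +Moderate gives 1S+1M = LP
  expect_true(is_priority_vus(parse_criteria("PS4"), "LDLR", panel))
  # supporting-only promotion also counts: 1S+1P -> +1P gives 1S+2P = LP
  expect_true(is_priority_vus(parse_criteria("PS4,PP1"), "LDLR", panel))
  # no single addition reaches LP
  expect_false(is_priority_vus(parse_criteria("PP3"), "LDLR", panel))
  # classic-FH-gene gate
  expect_false(is_priority_vus(parse_criteria("PS4"), "ABCG8", panel))
  # precondition: evidence must combine to VUS
  expect_error(is_priority_vus(parse_criteria("PVS1,PS3"), "LDLR", panel),
               class = "fh_triage_error")
})
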