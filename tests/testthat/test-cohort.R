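test_that("patients group by P/LP gene with FH precedence", {
  panel <- gene_panel()
  groups <- classify_patient(list(
    "LDLR",                       # classic FH carrier
    "LIPA",                       # phenocopy carrier (zygosity-independent)
    character(0),                 # no P/LP at all
    c("ABCG8", "LDLR"),           # both panels -> FH wins
    "TTN"                         # off-panel gene does not count
  ), panel)
  expect_equal(groups, c("FH_PLP", "PHENOCOPY_PLP", "NON_FH", "FH_PLP",
                         "NON_FH"))
})

test_that("published cross-tabulation summarizes to the printed yield", {
  s <- summarize_cohort(expand_table3())
  expect_equal(s$n, 339L)
  expect_equal(s$explained, 148)
  expect_equal(s$explained_pct, 43.7)
  tab <- s$table
  expect_equal(tab$size, c(73L, 7L, 259L))
  nf <- tab[tab$group == "NON_FH", ]
  expect_equal(c(nf$ldl_only, nf$lpa_only, nf$both), c(45L, 16L, 7L))

  y <- diagnostic_yield(s)
  expect_equal(y$monogenic_fh, 21.5)
  expect_equal(y$monogenic_total, 23.6)
  expect_equal(y$prs_of_non_monogenic, 26.3)
  expect_equal(y$prs_of_all, 20.1)
  expect_equal(y$combined, 43.7)

  # high-PRS carrier rows as printed per group: 9 (12.3%) FH LDL-C,
  # 4 (5.5%) FH LPA, 52 (20.1%) non-FH LDL-C including double hits
  fh <- tab[tab$group == "FH_PLP", ]
  expect_equal(fh$ldl_only + fh$both, 9L)
  expect_equal(round_half_up(100 * (fh$ldl_only + fh$both) / fh$size), 12.3)
  expect_equal(round_half_up(100 * (fh$lpa_only + fh$both) / fh$size), 5.5)
  expect_equal(nf$ldl_only + nf$both, 52L)
  expect_equal(round_half_up(100 * (nf$ldl_only + nf$both) / nf$size), 20.1)
})

test_that("degenerate cohorts are handled per contract", {
  none <- tibble::tibble(sample = c("a", "b"), group = "NON_FH",
                         high_ldl = FALSE, high_lpa = FALSE)
  s <- summarize_cohort(none)
  expect_equal(s$explained, 0)
  expect_equal(s$explained_pct, 0)

  one <- tibble::tibble(sample = "a", group = "FH_PLP",
                        high_ldl = TRUE, high_lpa = TRUE)
  s1 <- summarize_cohort(one)
  expect_equal(s1$explained, 1)
  expect_equal(s1$table$both[s1$table$group == "FH_PLP"], 1L)
  expect_error(diagnostic_yield(s1), class = "fh_cohort_error")  # no non-mono

  quarter <- tibble::tibble(sample = letters[1:4],
                            group = c("FH_PLP", rep("NON_FH", 3)),
                            high_ldl = FALSE, high_lpa = FALSE)
  y <- diagnostic_yield(summarize_cohort(quarter))
  expect_equal(unlist(y, use.names = FALSE), c(25, 25, 0, 0, 25))

  missing_prs <- tibble::tibble(sample = c("a", "b"), group = "NON_FH",
                                high_ldl = c(TRUE, NA), high_lpa = FALSE)
  expect_error(summarize_cohort(missing_prs), "b", class = "fh_cohort_error")

  # relatives drop from every denominator
  with_rel <- dplyr::bind_rows(none, tibble::tibble(
    sample = "rel1", group = "FH_PLP", high_ldl = FALSE, high_lpa = FALSE))
  with_rel$is_index <- c(TRUE, TRUE, FALSE)
  expect_equal(summarize_cohort(with_rel)$n, 2L)
})

test_that("rank AUC matches the all-pairs oracle and its symmetry law", {
  expect_equal(auc_rank(c(2, 3), c(0, 1)), 1)
  expect_equal(auc_rank(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(auc_rank(c(1, 3), c(2, 4)), oracle_auc(c(1, 3), c(2, 4)))
  expect_equal(oracle_auc(c(1, 3), c(2, 4)), 0.25)
  set.seed(9)
  for (i in 1:20) {
    a <- sample(1:50, 8, replace = TRUE)   # ties likely
    b <- sample(1:50, 11, replace = TRUE)
    expect_equal(auc_rank(a, b), oracle_auc(a, b))
  }
  a <- rnorm(15); b <- rnorm(9)            # tie-free
  expect_equal(auc_rank(a, b) + auc_rank(b, a), 1)
  expect_error(auc_rank(numeric(0), 1), class = "fh_cohort_error")
})

test_that("quartile homogeneity is Pearson chi-square without correction", {
  even <- matrix(c(10, 20, 10, 20, 10, 20, 10, 20), nrow = 2)
  res <- quartile_homogeneity(even)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$df, 3)

  sep <- matrix(c(10, 0, 0, 10), nrow = 2)
  res2 <- quartile_homogeneity(sep)
  expect_equal(res2$statistic, 20)
  expect_equal(res2$df, 1)

  set.seed(14)
  for (i in 1:10) {
    tab <- matrix(sample(1:30, 8), nrow = 2)
    got <- suppressWarnings(quartile_homogeneity(tab))  # small-cell warnings
    expect_equal(got$statistic, oracle_chisq(tab))
  }
  expect_error(quartile_homogeneity(matrix(c(0, 0, 5, 5), nrow = 2)),
               class = "fh_cohort_error")
})

test_that("explained count never decreases when the high-PRS cutoff is lowered", {
  set.seed(55)
  ref_ldl <- build_reference(rnorm(300))
  ref_lpa <- build_reference(rnorm(300))
  n <- 120
  patients <- tibble::tibble(
    sample = sprintf("p%d", seq_len(n)),
    group = sample(c("FH_PLP", "NON_FH"), n, TRUE, prob = c(0.2, 0.8)),
    ldl = rnorm(n, 0.3), lpa = rnorm(n, 0.1))
  explained_at <- function(q) {
    cut_l <- fhyield:::nearest_rank(ref_ldl$values, q)
    cut_a <- fhyield:::nearest_rank(ref_lpa$values, q)
    pat <- dplyr::mutate(patients, high_ldl = ldl > cut_l,
                         high_lpa = lpa > cut_a)
    summarize_cohort(pat)$explained
  }
  qs <- c(0.99, 0.95, 0.9, 0.8, 0.6, 0.4)
  vals <- vapply(qs, explained_at, numeric(1))
  expect_true(all(diff(vals) >= 0))
})
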