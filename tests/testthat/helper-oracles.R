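# Independent oracles used across the suite. These re-derive expected values
# by literal enumeration, kept deliberately separate from the package's own
# computation paths.

# --- ACMG combining-rule oracle -------------------------------------------
# Literal transcription of the combining table over strength tallies
# (vs, s, m, p pathogenic side; ba, bs, bp benign side), each rule spelled
# out separately.
oracle_acmg <- function(vs, s, m, p, ba, bs, bp) {
  pathogenic <-
    (vs >= 1 && s >= 1) ||
    (vs >= 1 && m >= 2) ||
    (vs >= 1 && m >= 1 && p >= 1) ||
    (vs >= 1 && p >= 2) ||
    (vs >= 2) ||
    (s >= 2) ||
    (s >= 1 && m >= 3) ||
    (s >= 1 && m == 2 && p >= 2) ||
    (s >= 1 && m == 1 && p >= 4)
  likely_pathogenic <-
    (vs == 1 && m >= 1) ||
    (s == 1 && (m == 1 || m == 2)) ||
    (s == 1 && p >= 2) ||
    (m >= 3) ||
    (m == 2 && p >= 2) ||
    (m == 1 && p >= 4)
  benign <- (ba >= 1) || (bs >= 2)
  likely_benign <- (bs == 1 && bp >= 1) || (bp >= 2)

  if ((pathogenic || likely_pathogenic) && (benign || likely_benign)) {
    return("VUS")
  }
  if (pathogenic) return("Pathogenic")
  if (likely_pathogenic) return("LikelyPathogenic")
  if (benign) return("Benign")
  if (likely_benign) return("LikelyBenign")
  "VUS"
}

# all strength tallies with at most `max_items` evidence items
all_evidence_tallies <- function(max_items = 6L) {
  g <- expand.grid(vs = 0:max_items, s = 0:max_items, m = 0:max_items,
                   p = 0:max_items, ba = 0:max_items, bs = 0:max_items,
                   bp = 0:max_items)
  g[rowSums(g) <= max_items, , drop = FALSE]
}

# build an acmg_evidence object realizing a tally, using dummy codes
evidence_from_tally <- function(vs, s, m, p, ba, bs, bp) {
  strengths <- c(rep("VeryStrong", vs), rep("Strong", s),
                 rep("Moderate", m), rep("Supporting", p),
                 rep("StandAloneBenign", ba), rep("BenignStrong", bs),
                 rep("BenignSupporting", bp))
  acmg_evidence(code = sprintf("X%02d", seq_along(strengths)),
                strength = strengths)
}

# --- brute-force rank AUC --------------------------------------------------
oracle_auc <- function(a, b) {
  wins <- 0
  for (x in a) for (y in b) {
    wins <- wins + (x > y) + 0.5 * (x == y)
  }
  wins / (length(a) * length(b))
}

# --- Pearson chi-square by direct O/E summation ----------------------------
oracle_chisq <- function(counts) {
  counts <- as.matrix(counts)
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  sum((counts - expected)^2 / expected)
}

# --- tiny VCF fixture writer ----------------------------------------------
write_test_vcf <- function(path, records, samples) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, records), path)
  path
}

class_rank <- function(x) {
  match(x, c("Benign", "LikelyBenign", "VUS", "LikelyPathogenic",
             "Pathogenic"))
}
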