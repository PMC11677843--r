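#' Genotype matrix container
#'
#' Holds decomposed, biallelic alt-allele counts for a cohort: one row per
#' (chrom, pos, ref, alt) variant, one column per sample, entries in
#' \{0, 1, 2, NA\} (NA = missing genotype).
#'
#' @param variants Tibble with columns `chrom`, `pos`, `ref`, `alt`.
#' @param alt_counts Integer matrix, `nrow(variants)` x `length(samples)`.
#' @param samples Character vector of sample identifiers (VCF header order).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(variants, alt_counts, samples) {
  variants <- tibble::as_tibble(variants)
  stopifnot(
    all(c("chrom", "pos", "ref", "alt") %in% names(variants)),
    nrow(alt_counts) == nrow(variants),
    ncol(alt_counts) == length(samples)
  )
  if (any(variants$pos < 1)) {
    abort_fh("variant positions must be 1-based (pos >= 1)", "fh_vcf_error")
  }
  if (any(variants$ref == variants$alt)) {
    abort_fh("ref and alt alleles must differ", "fh_vcf_error")
  }
  bad <- !(alt_counts %in% c(0L, 1L, 2L) | is.na(alt_counts))
  if (any(bad)) {
    abort_fh("alt_counts must be 0, 1, 2 or NA", "fh_vcf_error")
  }
  alt_counts <- matrix(as.integer(alt_counts), nrow = nrow(variants),
                       dimnames = list(variant_id(variants$chrom, variants$pos,
                                                  variants$ref, variants$alt),
                                       samples))
  structure(
    list(samples = samples, variants = variants, alt_counts = alt_counts),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$variants), " variants x ",
      length(x$samples), " samples\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(nrow(x$variants), length(x$samples))

# count of a given 1-based ALT allele index in one GT string; NA when any
# allele is missing ('.'); separator '/' or '|'
.gt_alt_count <- function(gt, allele_index) {
  alleles <- strsplit(gt, "[/|]")
  vapply(alleles, function(a) {
    if (length(a) == 0L || anyNA(a) || any(a == "." | a == "")) {
      return(NA_integer_)  # ./., .|. or absent field
    }
    sum(a == as.character(allele_index))
  }, integer(1))
}

#' Read a multi-sample VCF into a genotype matrix
#'
#' Reads GT fields from a VCF 4.x file, decomposing multiallelic records into
#' one biallelic variant per ALT allele: for a sample at a site with ALT
#' "A,G", the row for ALT A counts only allele index 1 and the row for G only
#' index 2, so the per-site total ALT count is preserved. Missing genotypes
#' ("./.") are recorded as NA, never as 0. REF is left unchanged (inputs are
#' assumed pre-normalized with a tool such as bcftools norm); no liftover.
#'
#' @param vcf_source Path to a VCF file (plain or bgzipped).
#' @param regions Optional tibble with columns `chrom`, `start`, `end`
#'   (1-based, inclusive) restricting the variants kept.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(vcf_source, regions = NULL) {
  vcf <- tryCatch(
    vcfR::read.vcfR(vcf_source, verbose = FALSE),
    error = function(e) {
      abort_fh(paste0("malformed VCF '", vcf_source, "': ", conditionMessage(e)),
               "fh_vcf_error")
    }
  )
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) {  # single-record VCFs come back as a bare vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  if (is.null(fix) || nrow(fix) == 0L) {
    abort_fh(paste0("VCF '", vcf_source, "' contains no variant records"),
             "fh_vcf_error")
  }
  gt_raw <- tryCatch(vcf@gt, error = function(e) NULL)
  if (is.null(gt_raw) || ncol(gt_raw) < 2L) {
    abort_fh(paste0("VCF '", vcf_source, "' has no sample genotype columns"),
             "fh_vcf_error")
  }
  samples <- colnames(gt_raw)[-1]
  # GT is mandatory first subfield here; strip any trailing FORMAT subfields
  gt <- apply(gt_raw[, -1, drop = FALSE], 2, function(col) sub(":.*$", "", col))
  gt <- matrix(gt, nrow = nrow(fix))

  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt_field <- fix[, "ALT"]
  if (any(is.na(pos))) {
    abort_fh(
      paste0("malformed VCF '", vcf_source, "': non-numeric POS at record ",
             which(is.na(pos))[1]),
      "fh_vcf_error"
    )
  }

  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(alt_field[i], ",", fixed = TRUE)[[1]]
    per_alt <- lapply(seq_along(alts), function(k) {
      list(chrom = chrom[i], pos = pos[i], ref = ref[i], alt = alts[k],
           counts = .gt_alt_count(gt[i, ], k))
    })
    rows[[i]] <- per_alt
  }
  rows <- unlist(rows, recursive = FALSE)
  variants <- tibble::tibble(
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    pos = vapply(rows, `[[`, integer(1), "pos"),
    ref = vapply(rows, `[[`, character(1), "ref"),
    alt = vapply(rows, `[[`, character(1), "alt")
  )
  counts <- do.call(rbind, lapply(rows, `[[`, "counts"))

  if (!is.null(regions)) {
    keep <- rep(FALSE, nrow(variants))
    vchrom <- norm_chrom(variants$chrom)
    for (j in seq_len(nrow(regions))) {
      keep <- keep | (vchrom == norm_chrom(regions$chrom[j]) &
                        variants$pos >= regions$start[j] &
                        variants$pos <= regions$end[j])
    }
    variants <- variants[keep, , drop = FALSE]
    counts <- counts[keep, , drop = FALSE]
  }
  genotype_matrix(variants, counts, samples)
}

#' Write a genotype matrix to a VCF 4.2 file
#'
#' Serializes alt-allele counts back to GT-only VCF records (0/0, 0/1, 1/1,
#' ./.). Each decomposed variant is written as its own biallelic record, so
#' reading the file back reproduces the alt counts exactly.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  body <- vapply(seq_len(nrow(gm$variants)), function(i) {
    counts <- gm$alt_counts[i, ]
    gt <- ifelse(is.na(counts), "./.", gt_code[as.character(counts)])
    paste(c(gm$variants$chrom[i], gm$variants$pos[i], ".",
            gm$variants$ref[i], gm$variants$alt[i], ".", "PASS", ".", "GT",
            gt), collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}
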