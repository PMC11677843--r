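#' Parse a PGS-Catalog-format scoring file
#'
#' Scoring files are TSV with '#'-prefixed metadata header lines followed by
#' a column-header row. The columns `effect_allele` and `effect_weight` are
#' required; `other_allele` is optional. Positions come from
#' `chr_name`/`chr_position`, with the harmonized `hm_chr`/`hm_pos` columns
#' preferred when present. An optional `rsID` column is carried through.
#'
#' @param source Path to a scoring file.
#' @return Tibble with columns `variant_id`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele` (NA when absent), `effect_weight`.
#' @export
parse_scorefile <- function(source) {
  lines <- readLines(source)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) < 1L) {
    abort_fh(paste0("scoring file '", source, "' has no column-header row"),
             "fh_scorefile_error")
  }
  tab <- utils::read.delim(text = body, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  for (col in c("effect_allele", "effect_weight")) {
    if (!col %in% names(tab)) {
      abort_fh(paste0("scoring file '", source, "' lacks required column '",
                      col, "'"), "fh_scorefile_error")
    }
  }
  chrom <- if ("hm_chr" %in% names(tab)) tab$hm_chr else tab[["chr_name"]]
  pos_chr <- if ("hm_pos" %in% names(tab)) tab$hm_pos else tab[["chr_position"]]
  if (is.null(chrom) || is.null(pos_chr)) {
    abort_fh(paste0("scoring file '", source,
                    "' lacks position columns (chr_name/chr_position or hm_chr/hm_pos)"),
             "fh_scorefile_error")
  }
  weight <- suppressWarnings(as.numeric(tab$effect_weight))
  bad <- which(is.na(weight) | !is.finite(weight))
  if (length(bad) > 0L) {
    abort_fh(paste0("unparseable effect_weight in scoring file '", source,
                    "' at data row(s) ", paste(bad, collapse = ", ")),
             "fh_scorefile_error")
  }
  if (any(!nzchar(tab$effect_allele))) {
    abort_fh("empty effect_allele in scoring file", "fh_scorefile_error")
  }
  other <- if ("other_allele" %in% names(tab)) tab$other_allele else NA_character_
  other[!is.na(other) & !nzchar(other)] <- NA_character_
  tibble::tibble(
    variant_id = if ("rsID" %in% names(tab)) tab$rsID else NA_character_,
    chrom = as.character(chrom),
    pos = as.integer(pos_chr),
    effect_allele = toupper(tab$effect_allele),
    other_allele = toupper(other),
    effect_weight = weight
  )
}

#' Write a scoring-file tibble in PGS-Catalog dialect
#'
#' @param records Tibble as returned by [parse_scorefile()].
#' @param path Output path.
#' @param name Score label written into the metadata header.
#' @return `path`, invisibly.
#' @export
write_scorefile <- function(records, path, name = "score") {
  header <- c(
    "### PGS CATALOG SCORING FILE - format dialect",
    paste0("#pgs_name=", name),
    "#genome_build=GRCh38"
  )
  cols <- c("rsID", "chr_name", "chr_position", "effect_allele",
            "other_allele", "effect_weight")
  body <- data.frame(
    rsID = ifelse(is.na(records$variant_id), "", records$variant_id),
    chr_name = records$chrom,
    chr_position = records$pos,
    effect_allele = records$effect_allele,
    other_allele = ifelse(is.na(records$other_allele), "",
                          records$other_allele),
    effect_weight = format(records$effect_weight, trim = TRUE, digits = 15,
                           scientific = FALSE)
  )
  lines <- c(header, paste(cols, collapse = "\t"),
             do.call(paste, c(body, sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

.ensure_key <- function(tab, label) {
  if (".key" %in% names(tab)) return(tab)
  key <- variant_id(tab$chrom, tab$pos, tab$ref, tab$alt)
  dup <- unique(key[duplicated(key)])
  if (length(dup) > 0L) {
    abort_fh(paste0("duplicate variant keys in ", label, " table: ",
                    paste(dup, collapse = "; ")), "fh_table_error")
  }
  tab$.key <- key
  tab
}

.read_keyed_tsv <- function(source, required, label) {
  # allele columns must never be guessed (a lone "T" is not a logical)
  tab <- readr::read_tsv(
    source, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(chrom = "c", ref = "c", alt = "c",
                            .default = readr::col_guess()))
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    abort_fh(paste0(label, " table '", source, "' lacks column(s): ",
                    paste(missing, collapse = ", ")), "fh_table_error")
  }
  key <- variant_id(tab$chrom, tab$pos, tab$ref, tab$alt)
  dup <- unique(key[duplicated(key)])
  if (length(dup) > 0L) {
    abort_fh(paste0("duplicate variant keys in ", label, " table: ",
                    paste(dup, collapse = "; ")), "fh_table_error")
  }
  tab$.key <- key
  tab
}

#' Read an annotation table
#'
#' Expected columns: chrom, pos, ref, alt, gene, consequence, popmax_faf
#' (fraction in \[0,1\], may be empty = frequency absent from gnomAD), rsid.
#'
#' @param source Path to a TSV file.
#' @return Tibble keyed by variant.
#' @export
read_annotation <- function(source) {
  tab <- .read_keyed_tsv(source, c("chrom", "pos", "ref", "alt", "gene",
                                   "consequence", "popmax_faf"), "annotation")
  tab$popmax_faf <- as.numeric(tab$popmax_faf)
  out_of_range <- !is.na(tab$popmax_faf) &
    (tab$popmax_faf < 0 | tab$popmax_faf > 1)
  if (any(out_of_range)) {
    abort_fh("popmax_faf outside [0, 1] in annotation table", "fh_table_error")
  }
  tab
}

#' Read a ClinVar-style classification table
#'
#' Expected columns: chrom, pos, ref, alt, classification (ClinVar germline
#' aggregate, e.g. "Pathogenic", "Pathogenic/Likely pathogenic", "VUS",
#' "Conflicting"), gold_stars (0-4 review-status stars), submitter_count,
#' clinvar_id.
#'
#' @param source Path to a TSV file.
#' @return Tibble keyed by variant.
#' @export
read_clinvar <- function(source) {
  tab <- .read_keyed_tsv(source, c("chrom", "pos", "ref", "alt",
                                   "classification", "gold_stars",
                                   "submitter_count"), "ClinVar")
  if (any(!is.na(tab$gold_stars) & (tab$gold_stars < 0 | tab$gold_stars > 4))) {
    abort_fh("gold_stars outside 0-4 in ClinVar table", "fh_table_error")
  }
  tab
}

#' Read an ACMG/AMP evidence table
#'
#' Expected columns: chrom, pos, ref, alt, criteria — a comma-separated list
#' of criterion codes, optionally with modified strengths (e.g.
#' "PVS1_Strong,PM2_Supporting").
#'
#' @param source Path to a TSV file.
#' @return Tibble keyed by variant.
#' @export
read_evidence <- function(source) {
  .read_keyed_tsv(source, c("chrom", "pos", "ref", "alt", "criteria"),
                  "evidence")
}

#' Join annotation, ClinVar and evidence tables on the variant key
#'
#' Left-joins onto the annotation (patient variant) list. Variants without a
#' ClinVar row get classification "absent" with 0 stars/submitters; variants
#' without an evidence row get an empty criteria string.
#'
#' @param annotation_source,clinvar_source,evidence_source TSV paths, or
#'   tibbles already read by the respective readers.
#' @return Tibble with one row per annotated variant.
#' @export
read_tables <- function(annotation_source, clinvar_source, evidence_source) {
  ann <- if (is.character(annotation_source)) read_annotation(annotation_source) else .ensure_key(annotation_source, "annotation")
  clv <- if (is.character(clinvar_source)) read_clinvar(clinvar_source) else .ensure_key(clinvar_source, "ClinVar")
  evd <- if (is.character(evidence_source)) read_evidence(evidence_source) else .ensure_key(evidence_source, "evidence")

  clv_join <- dplyr::select(clv, ".key", "classification", "gold_stars",
                            "submitter_count",
                            dplyr::any_of("clinvar_id"))
  evd_join <- dplyr::select(evd, ".key", "criteria")
  out <- ann |>
    dplyr::left_join(clv_join, by = ".key") |>
    dplyr::left_join(evd_join, by = ".key")
  out$classification[is.na(out$classification)] <- "absent"
  out$gold_stars[is.na(out$gold_stars)] <- 0L
  out$submitter_count[is.na(out$submitter_count)] <- 0L
  out$criteria[is.na(out$criteria)] <- ""
  out
}
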