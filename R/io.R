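#' Read somatic variants from a VCF file
#'
#' Reads a VCF v4.2 with per-sample `DP` and `AD` FORMAT fields and returns
#' one row per ALT allele per site (multi-allelic sites are decomposed).
#' Indel records are left-normalized (shared prefix/suffix trimmed down to
#' the anchor base) so variant keys are deterministic. The variant allele
#' frequency is computed from tumor `AD`/`DP`. Site-level base quality is
#' taken from the INFO key `MBQ` when present, falling back to the record
#' `QUAL`; the column `baseq_source` records which was used. Strand bias is
#' read from INFO `SOR`. Missing annotations are stored as `NA`, never as 0.
#'
#' @param path Path to a VCF file.
#' @param tumor_sample Name of the tumor sample column.
#' @param normal_sample Name of the matched-normal sample column, or `NULL`
#'   for tumor-only runs (cell lines without a matched normal).
#' @return A tibble with columns `chrom`, `pos`, `ref_allele`, `alt_allele`,
#'   `variant_class` (`"SNV"`, `"insertion"`, `"deletion"`), `tumor_dp`,
#'   `tumor_ad_alt`, `normal_dp`, `normal_ad_ref`, `base_quality`,
#'   `baseq_source`, `sor`, `vaf`. Attribute `tumor_only` records whether a
#'   normal sample was available.
#' @export
read_vcf <- function(path, tumor_sample, normal_sample = NULL) {
  if (!file.exists(path)) abort(paste0("VCF file not found: ", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)   # single-variant files drop dims
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  samples <- colnames(v@gt)[-1]
  if (!tumor_sample %in% samples) {
    abort(paste0("Tumor sample '", tumor_sample, "' not present in VCF (",
                 "samples: ", paste(samples, collapse = ", "), ")."))
  }
  if (!is.null(normal_sample) && !normal_sample %in% samples) {
    abort(paste0("Normal sample '", normal_sample, "' not present in VCF."))
  }

  as_gt_matrix <- function(m) {
    if (is.null(dim(m))) matrix(m, nrow = 1, dimnames = list(NULL, names(m)))
    else m
  }
  dp <- as_gt_matrix(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  ad <- as_gt_matrix(vcfR::extract.gt(v, element = "AD"))
  if (all(is.na(dp[, tumor_sample])) || all(is.na(ad[, tumor_sample]))) {
    abort("Tumor sample has no DP/AD FORMAT fields; cannot compute VAF.")
  }
  sor <- suppressWarnings(as.numeric(vcfR::extract.info(v, "SOR")))
  mbq <- suppressWarnings(as.numeric(vcfR::extract.info(v, "MBQ")))
  qual <- suppressWarnings(as.numeric(fix$QUAL))

  rows <- purrr::map_dfr(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    t_ad <- parse_ad(ad[i, tumor_sample])
    t_dp <- dp[i, tumor_sample]
    if (is.na(t_dp) || length(t_ad) < length(alts) + 1L) {
      abort(paste0("Tumor DP/AD missing or malformed at ",
                   fix$CHROM[i], ":", fix$POS[i]))
    }
    n_dp <- NA_real_
    n_ad_ref <- NA_real_
    if (!is.null(normal_sample)) {
      n_dp <- dp[i, normal_sample]
      n_ad <- parse_ad(ad[i, normal_sample])
      if (length(n_ad) >= 1L) n_ad_ref <- n_ad[1]
    }
    bq <- if (!is.na(mbq[i])) mbq[i] else qual[i]
    bq_src <- if (!is.na(mbq[i])) "MBQ" else if (!is.na(qual[i])) "QUAL" else NA_character_
    purrr::map_dfr(seq_along(alts), function(j) {
      norm <- normalize_variant(fix$REF[i], alts[j], as.integer(fix$POS[i]))
      tibble(
        chrom = fix$CHROM[i],
        pos = norm$pos,
        ref_allele = norm$ref,
        alt_allele = norm$alt,
        variant_class = variant_class_of(norm$ref, norm$alt),
        tumor_dp = as.integer(t_dp),
        tumor_ad_alt = as.integer(t_ad[j + 1L]),
        normal_dp = as.integer(n_dp),
        normal_ad_ref = as.integer(n_ad_ref),
        base_quality = bq,
        baseq_source = bq_src,
        sor = sor[i],
        vaf = if (t_dp > 0) t_ad[j + 1L] / t_dp else NA_real_
      )
    })
  })
  attr(rows, "tumor_only") <- is.null(normal_sample)
  rows
}

parse_ad <- function(x) {
  if (is.na(x)) return(numeric(0))
  suppressWarnings(as.numeric(strsplit(x, ",", fixed = TRUE)[[1]]))
}

variant_class_of <- function(ref, alt) {
  if (nchar(ref) == 1L && nchar(alt) == 1L) "SNV"
  else if (nchar(alt) > nchar(ref)) "insertion"
  else "deletion"
}

# Trim a shared suffix then a shared prefix (keeping one anchor base),
# shifting pos by the trimmed prefix. Left-alignment for the simple
# (non-repetitive) representations handled here.
normalize_variant <- function(ref, alt, pos) {
  ref <- toupper(ref); alt <- toupper(alt)
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substring(ref, nchar(ref)) == substring(alt, nchar(alt))) {
    ref <- substring(ref, 1L, nchar(ref) - 1L)
    alt <- substring(alt, 1L, nchar(alt) - 1L)
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substring(ref, 1L, 1L) == substring(alt, 1L, 1L)) {
    ref <- substring(ref, 2L)
    alt <- substring(alt, 2L)
    pos <- pos + 1L
  }
  list(ref = ref, alt = alt, pos = pos)
}

#' Read a gene-expression table
#'
#' Reads a tab-separated expression table with at least `gene_id` and `TPM`
#' columns (case-insensitive); `gene_symbol` and `RPKM` are carried through
#' when present.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `gene_id`, `gene_symbol`, `tpm`, `rpkm`.
#' @export
read_expression <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  nm <- tolower(names(tab))
  names(tab) <- nm
  if (!"gene_id" %in% nm) abort("Expression table lacks a gene_id column.")
  if (!"tpm" %in% nm) abort("Expression table lacks a TPM column.")
  out <- tibble(
    gene_id = as.character(tab$gene_id),
    gene_symbol = if ("gene_symbol" %in% nm) as.character(tab$gene_symbol)
                  else as.character(tab$gene_id),
    tpm = as.numeric(tab$tpm),
    rpkm = if ("rpkm" %in% nm) as.numeric(tab$rpkm) else NA_real_
  )
  dup <- out$gene_id[duplicated(out$gene_id)]
  if (length(dup)) {
    abort(paste0("Duplicate gene_id in expression table: ",
                 paste(unique(dup), collapse = ", ")))
  }
  if (any(is.na(out$tpm))) abort("Non-numeric TPM values in expression table.")
  if (any(out$tpm < 0)) {
    bad <- out$gene_id[out$tpm < 0]
    abort(paste0("Negative TPM for gene(s): ", paste(bad, collapse = ", ")))
  }
  out
}

CANDIDATE_COLUMNS <- c(
  "neoantigen_id", "hla_allele", "allele_frequency", "amino_acid_change",
  "gene_symbol", "peptide_position", "mut_mhc_ic50", "priority_score",
  "augmented_peptide", "synthesis_failed"
)

#' Write and read ranked candidate tables
#'
#' Serializes scored neoantigen records to a TSV with a fixed column order
#' (one row per candidate: allele, allele frequency, amino-acid change, gene,
#' position of the mutated residue in the best minimal epitope, mutant IC50,
#' priority score, augmented long peptide, synthesis flag). Writing then
#' reading reproduces the records.
#'
#' @param records A tibble of candidate records carrying the columns listed
#'   above (extra columns are dropped on write).
#' @param path Output file path.
#' @return `write_candidates()` returns `path` invisibly;
#'   `read_candidates()` returns the candidate tibble.
#' @export
write_candidates <- function(records, path) {
  missing <- setdiff(CANDIDATE_COLUMNS, names(records))
  if (length(missing)) {
    abort(paste0("Candidate records lack column(s): ",
                 paste(missing, collapse = ", ")))
  }
  readr::write_tsv(records[, CANDIDATE_COLUMNS], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_candidates
#' @export
read_candidates <- function(path) {
  readr::read_tsv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      neoantigen_id = readr::col_character(),
      hla_allele = readr::col_character(),
      allele_frequency = readr::col_double(),
      amino_acid_change = readr::col_character(),
      gene_symbol = readr::col_character(),
      peptide_position = readr::col_integer(),
      mut_mhc_ic50 = readr::col_double(),
      priority_score = readr::col_double(),
      augmented_peptide = readr::col_character(),
      synthesis_failed = readr::col_logical()
    )
  )
}

#' Read a precomputed peptide-MHC binding table
#'
#' Loads a TSV of externally computed binding results, for use with
#' [table_predictor()]. Required columns: `peptide`, `allele`, `ic50_nm`
#' (case-insensitive; `ic50_nM` accepted); optional `percent_rank`.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `peptide`, `allele`, `ic50`, `percent_rank`.
#' @export
read_binding_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tab) <- tolower(names(tab))
  need <- c("peptide", "allele")
  if (!all(need %in% names(tab)) || !any(c("ic50_nm", "ic50") %in% names(tab))) {
    abort("Binding table needs columns peptide, allele, ic50_nM.")
  }
  tibble(
    peptide = toupper(as.character(tab$peptide)),
    allele = as.character(tab$allele),
    ic50 = as.numeric(if ("ic50_nm" %in% names(tab)) tab$ic50_nm else tab$ic50),
    percent_rank = if ("percent_rank" %in% names(tab))
      as.numeric(tab$percent_rank) else NA_real_
  )
}

#' Read a key/value configuration file of thresholds and weights
#'
#' Reads a YAML configuration carrying any of the filtering thresholds
#' (see [filter_thresholds()]) under `thresholds:` and scoring weights
#' (see [scoring_weights()]) under `weights:`.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `thresholds` and `weights`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  list(
    thresholds = do.call(filter_thresholds, cfg$thresholds %||% list()),
    weights = do.call(scoring_weights, cfg$weights %||% list())
  )
}
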