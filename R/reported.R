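REPORTED_TABLES <- c(
  "4t1_rna" = "candidates_4t1_rna.tsv",
  "4t1_conventional" = "candidates_4t1_conventional.tsv",
  "llc_rna" = "candidates_llc_rna.tsv",
  "llc_conventional" = "candidates_llc_conventional.tsv",
  "patient_rna" = "candidates_patient_rna.tsv"
)

#' Published top-candidate tables
#'
#' Loads the packaged transcriptions of published neoantigen screens in
#' mouse breast cancer (4T1, BALB/c H-2d background, 31-mer peptides),
#' mouse lung cancer (LLC, C57BL/6 H-2b background, 27-mer peptides) and
#' one breast-cancer patient (HLA-typed, 31-mer peptides), each comparing
#' an RNA-seq-only calling route with a conventional WES+RNA route. They
#' serve as worked examples and fixtures for the long-peptide designer, the
#' synthesis-failure accounting and the set-comparison tools.
#'
#' @param table Table selector: an integer 1-5 or one of `"4t1_rna"`,
#'   `"4t1_conventional"`, `"llc_rna"`, `"llc_conventional"`,
#'   `"patient_rna"`.
#' @return A tibble with columns `neoantigen_id`, `cross_id` (matching id
#'   in the companion list, `NA` if unique to this list),
#'   `synthesis_failed`, `hla_allele`, `allele_frequency`,
#'   `amino_acid_change`, `gene_symbol`, `peptide_position`,
#'   `mut_mhc_ic50`, `priority_score`, `augmented_peptide`, plus a derived
#'   `variant_key` (`GENE:CHANGE`; these tables print no residue
#'   coordinate, so the key is gene + amino-acid change).
#' @export
reported_candidates <- function(table) {
  if (is.numeric(table)) {
    if (!table %in% 1:5) abort("`table` must be 1..5 or a table name.")
    table <- names(REPORTED_TABLES)[table]
  }
  if (!table %in% names(REPORTED_TABLES)) {
    abort(paste0("Unknown table '", table, "'. Use 1-5 or one of: ",
                 paste(names(REPORTED_TABLES), collapse = ", ")))
  }
  path <- system.file("extdata", REPORTED_TABLES[[table]], package = "rnaneo",
                      mustWork = TRUE)
  out <- readr::read_tsv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      neoantigen_id = readr::col_character(),
      cross_id = readr::col_character(),
      synthesis_failed = readr::col_logical(),
      hla_allele = readr::col_character(),
      allele_frequency = readr::col_double(),
      amino_acid_change = readr::col_character(),
      gene_symbol = readr::col_character(),
      peptide_position = readr::col_integer(),
      mut_mhc_ic50 = readr::col_double(),
      priority_score = readr::col_double(),
      augmented_peptide = readr::col_character()
    )
  )
  out$variant_key <- paste0(toupper(out$gene_symbol), ":",
                            toupper(out$amino_acid_change))
  attr(out, "table") <- table
  attr(out, "window") <- if (table %in% c("llc_rna", "llc_conventional")) 27L else 31L
  out
}

#' @rdname reported_candidates
#' @return `reported_table_checksums()` returns the md5 checksum of each
#'   packaged table file, used to guard the transcriptions against drift.
#' @export
reported_table_checksums <- function() {
  paths <- vapply(REPORTED_TABLES, function(f) {
    system.file("extdata", f, package = "rnaneo", mustWork = TRUE)
  }, character(1))
  sums <- tools::md5sum(paths)
  setNames(unname(sums), names(REPORTED_TABLES))
}
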