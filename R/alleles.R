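#' Parse MHC/HLA allele names
#'
#' Accepts the allele spellings produced by common HLA typing tools and used
#' in mouse immunogenetics: four-digit HLA names (`"HLA-A02:07"`),
#' underscore-separated class II names (`"DRB1_1501"`), paired class II
#' alpha/beta names (`"HLA-DPA10202-DPB10202"`), and mouse H-2 haplotype
#' alleles (`"H-2-Kd"`, `"H2-Ld"`, `"H-2-IAb"`). Parsing is lossless:
#' `raw_name` is kept verbatim so that re-serializing a parsed allele is the
#' identity.
#'
#' @param x Character vector of allele names.
#' @return A tibble with one row per allele and columns `raw_name`,
#'   `species` (`"human"` or `"mouse"`), `mhc_class` (`"I"` or `"II"`),
#'   `locus` (for paired class II names, the alpha and beta loci joined with
#'   `"/"`), `paired` (logical), `alpha_locus` and `beta_locus` (`NA` unless
#'   paired).
#' @examples
#' parse_alleles(c("H-2-Kd", "HLA-A02:07", "DRB1_1501", "HLA-DPA10202-DPB10202"))
#' @export
parse_alleles <- function(x) {
  if (!is.character(x) || length(x) == 0) {
    abort("`x` must be a non-empty character vector of allele names.")
  }
  purrr::map_dfr(x, parse_allele_one)
}

#' @rdname parse_alleles
#' @param name A single allele name.
#' @export
parse_allele <- function(name) {
  stopifnot(length(name) == 1)
  parse_alleles(name)
}

CLASS_II_LOCI <- c("DRA", "DRB1", "DRB3", "DRB4", "DRB5",
                   "DQA1", "DQB1", "DPA1", "DPB1", "H2-IA", "H2-IE")

parse_allele_one <- function(name) {
  raw <- name
  if (is.na(name) || !nzchar(trimws(name))) {
    abort("Allele name is empty.")
  }
  s <- trimws(name)

  # Mouse H-2 alleles: H-2-Kd / H2-Kb / H-2-IAb / H2-Ld
  m <- stringr::str_match(s, "^[Hh]-?2-?(K|D|L|IA|IE)([a-z])$")
  if (!is.na(m[1, 1])) {
    locus <- paste0("H2-", m[1, 2])
    return(tibble(
      raw_name = raw, species = "mouse",
      mhc_class = if (m[1, 2] %in% c("IA", "IE")) "II" else "I",
      locus = locus, paired = FALSE,
      alpha_locus = NA_character_, beta_locus = NA_character_
    ))
  }

  # Paired human class II: HLA-DPA10202-DPB10202, HLA-DQA10102-DQB10303
  m <- stringr::str_match(
    s, "^(?:HLA-)?(D[PQ]A\\d)\\*?(\\d{4})-(D[PQ]B\\d)\\*?(\\d{4})$"
  )
  if (!is.na(m[1, 1])) {
    return(tibble(
      raw_name = raw, species = "human", mhc_class = "II",
      locus = paste0(m[1, 2], "/", m[1, 4]), paired = TRUE,
      alpha_locus = m[1, 2], beta_locus = m[1, 4]
    ))
  }

  # Underscore dialect: DRB1_1501, DQB1_0303
  m <- stringr::str_match(s, "^(?:HLA-)?(DRA|DRB\\d|DQA\\d|DQB\\d|DPA\\d|DPB\\d)_(\\d{4})$")
  if (!is.na(m[1, 1])) {
    locus <- m[1, 2]
    if (!locus %in% CLASS_II_LOCI) {
      abort(paste0("Unrecognized class II locus in allele name: '", locus, "'"))
    }
    return(tibble(
      raw_name = raw, species = "human", mhc_class = "II",
      locus = locus, paired = FALSE,
      alpha_locus = NA_character_, beta_locus = NA_character_
    ))
  }

  # Human class I: HLA-A02:07, HLA-B*15:27, A02:07
  m <- stringr::str_match(s, "^(?:HLA-)?([ABC])\\*?(\\d{2}):?(\\d{2,3})$")
  if (!is.na(m[1, 1])) {
    return(tibble(
      raw_name = raw, species = "human", mhc_class = "I",
      locus = m[1, 2], paired = FALSE,
      alpha_locus = NA_character_, beta_locus = NA_character_
    ))
  }

  # Single class II with colon/star notation: HLA-DRB1*09:01
  m <- stringr::str_match(s, "^(?:HLA-)?(D[RQP][AB]\\d?)\\*?(\\d{2}):?(\\d{2})$")
  if (!is.na(m[1, 1]) && m[1, 2] %in% CLASS_II_LOCI) {
    return(tibble(
      raw_name = raw, species = "human", mhc_class = "II",
      locus = m[1, 2], paired = FALSE,
      alpha_locus = NA_character_, beta_locus = NA_character_
    ))
  }

  abort(paste0("Unrecognized MHC allele name: '", raw,
               "' (unknown locus prefix)."))
}

#' Serialize parsed alleles back to their original names
#'
#' The inverse of [parse_alleles()]: returns the verbatim `raw_name` column,
#' so `serialize_alleles(parse_alleles(x))` is identical to `x`.
#'
#' @param alleles A tibble from [parse_alleles()].
#' @return Character vector of allele names.
#' @export
serialize_alleles <- function(alleles) {
  stopifnot(is.data.frame(alleles), "raw_name" %in% names(alleles))
  alleles$raw_name
}

#' Read a typed MHC allele list
#'
#' Reads either a plain newline-separated list of allele names, or the
#' two-column genotype dialect written by RNA-seq HLA typing tools
#' (tab-separated `locus<TAB>allele`, where the allele carries four digits,
#' e.g. `A<TAB>A*02:07`). Lines starting with `#` are ignored.
#'
#' @param path Path to the allele file.
#' @return A parsed allele tibble (see [parse_alleles()]).
#' @export
read_alleles <- function(path) {
  lines <- readr::read_lines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) abort(paste0("No allele entries found in ", path))
  has_tab <- grepl("\t", lines)
  names <- ifelse(
    has_tab,
    vapply(strsplit(lines, "\t"), function(f) {
      a <- trimws(f[[2]])
      if (grepl("^(HLA-|H-?2)", a) || grepl("_", a)) a else paste0("HLA-", gsub("\\*", "", a))
    }, character(1)),
    lines
  )
  parse_alleles(names)
}
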