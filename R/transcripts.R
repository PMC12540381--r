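#' Read transcript models from GFF3 + genome FASTA
#'
#' Builds protein-coding transcript models from the CDS features of a GFF3
#' file and a genome FASTA. Each model carries its ordered CDS intervals,
#' the genomic sequence of each interval, and the translated protein
#' (reverse-strand transcripts are reverse-complemented before translation).
#' Models whose spliced CDS length is not a multiple of three, or whose
#' translation contains an internal stop, fail validation.
#'
#' @param gff3_path Path to a GFF3 file with `CDS` features carrying
#'   `Parent` (transcript id) and, optionally, `gene_name` attributes.
#' @param fasta_path Path to the genome FASTA.
#' @return A tibble with columns `transcript_id`, `gene_symbol`, `chrom`,
#'   `strand`, `cds` (list column of tibbles `start`, `end`, `seq`, ordered
#'   by genomic start) and `protein_seq`.
#' @export
read_transcript_models <- function(gff3_path, fasta_path) {
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  lines <- readr::read_lines(gff3_path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  rows <- purrr::map_dfr(f, function(x) {
    if (length(x) < 9 || x[3] != "CDS") return(NULL)
    attrs <- parse_gff_attrs(x[9])
    tibble(
      chrom = x[1], start = as.integer(x[4]), end = as.integer(x[5]),
      strand = x[7],
      transcript_id = sub("^transcript:", "", attrs[["Parent"]] %||%
                            attrs[["transcript_id"]] %||% attrs[["ID"]]),
      gene_symbol = attrs[["gene_name"]] %||% attrs[["gene_id"]] %||% NA_character_
    )
  })
  if (nrow(rows) == 0) abort(paste0("No CDS features found in ", gff3_path))

  models <- rows %>%
    group_by(.data$transcript_id) %>%
    dplyr::group_map(function(g, key) {
      g <- arrange(g, .data$start)
      chrom <- g$chrom[1]
      if (!chrom %in% names(genome)) {
        abort(paste0("Contig ", chrom, " absent from FASTA."))
      }
      seqs <- vapply(seq_len(nrow(g)), function(i) {
        as.character(Biostrings::subseq(genome[[chrom]], g$start[i], g$end[i]))
      }, character(1))
      cds_tab <- tibble(start = g$start, end = g$end, seq = seqs)
      protein <- translate_model(cds_tab, g$strand[1])
      tibble(
        transcript_id = key$transcript_id,
        gene_symbol = g$gene_symbol[1],
        chrom = chrom,
        strand = g$strand[1],
        cds = list(cds_tab),
        protein_seq = protein
      )
    }) %>%
    bind_rows()
  validate_transcript_models(models)
  models
}

parse_gff_attrs <- function(s) {
  kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  setNames(
    vapply(kv, function(p) if (length(p) > 1) p[2] else NA_character_, character(1)),
    vapply(kv, `[`, character(1), 1)
  )
}

# Splice genomic-order interval sequences and translate in coding
# orientation; drops the trailing stop.
translate_model <- function(cds, strand) {
  spliced <- paste(cds$seq, collapse = "")
  if (strand == "-") spliced <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(spliced)))
  aa <- as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAString(spliced))))
  sub("\\*$", "", aa)
}

#' Validate transcript models
#'
#' Checks that each model's spliced CDS length is divisible by three and
#' that the stored protein has no internal stop codons.
#'
#' @param models A transcript model tibble (see [read_transcript_models()]).
#' @return `models`, invisibly; aborts on inconsistency.
#' @export
validate_transcript_models <- function(models) {
  for (i in seq_len(nrow(models))) {
    len <- sum(models$cds[[i]]$end - models$cds[[i]]$start + 1L)
    if (len %% 3L != 0L) {
      abort(paste0("Transcript ", models$transcript_id[i],
                   ": CDS length ", len, " not divisible by 3."))
    }
    if (grepl("\\*", models$protein_seq[i])) {
      abort(paste0("Transcript ", models$transcript_id[i],
                   ": internal stop codon in translation."))
    }
    if (!nchar(models$protein_seq[i]) %in% c(len %/% 3L, len %/% 3L - 1L)) {
      abort(paste0("Transcript ", models$transcript_id[i],
                   ": protein length inconsistent with CDS length."))
    }
  }
  invisible(models)
}
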