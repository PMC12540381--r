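#' Annotate somatic variants with protein consequences
#'
#' Maps each variant onto the transcript models it overlaps and derives the
#' codon-accurate protein consequence (standard nuclear code): `missense`,
#' `synonymous`, `stop_gain`, `inframe_indel`, or `frameshift` (translated
#' to the first novel stop). Variants outside any CDS get consequence class
#' `none` rather than an error. When a variant hits several transcripts of
#' one gene, the longest transcript's consequence is kept, so downstream
#' keys are gene-level.
#'
#' @param variants Variant tibble (see [read_vcf()]).
#' @param models Transcript model tibble (see [read_transcript_models()]).
#' @return A tibble with one row per (variant, gene): variant coordinates
#'   plus `gene_symbol`, `transcript_id`, `aa_pos`, `ref_aa`, `alt_aa`
#'   (`NA` for indels), `consequence_class`, `wt_protein`, `mutant_protein`,
#'   `vaf` (carried through), and `variant_key` (`GENE:pos:REF/ALT`,
#'   case-normalized).
#' @export
annotate_variants <- function(variants, models) {
  v <- as_tibble(variants)
  out <- purrr::map_dfr(seq_len(nrow(v)), function(i) {
    hits <- overlapping_models(v[i, ], models)
    if (nrow(hits) == 0) {
      return(consequence_row(v[i, ], NA_character_, NA_character_,
                             class = "none"))
    }
    # one consequence per gene: keep the longest transcript
    hits <- hits %>%
      mutate(plen = nchar(.data$protein_seq)) %>%
      group_by(.data$gene_symbol) %>%
      arrange(desc(.data$plen), .data$transcript_id) %>%
      slice_head(n = 1) %>%
      ungroup()
    purrr::map_dfr(seq_len(nrow(hits)), function(j) {
      annotate_one(v[i, ], hits[j, ])
    })
  })
  out
}

overlapping_models <- function(variant, models) {
  span_end <- variant$pos + nchar(variant$ref_allele) - 1L
  keep <- vapply(seq_len(nrow(models)), function(i) {
    m <- models[i, ]
    m$chrom == variant$chrom &&
      any(m$cds[[1]]$start <= variant$pos & span_end <= m$cds[[1]]$end)
  }, logical(1))
  models[keep, ]
}

consequence_row <- function(variant, gene, transcript, class,
                            aa_pos = NA_integer_, ref_aa = NA_character_,
                            alt_aa = NA_character_,
                            wt_protein = NA_character_,
                            mutant_protein = NA_character_) {
  tibble(
    chrom = variant$chrom, pos = variant$pos,
    ref_allele = variant$ref_allele, alt_allele = variant$alt_allele,
    gene_symbol = gene, transcript_id = transcript,
    consequence_class = class, aa_pos = as.integer(aa_pos),
    ref_aa = ref_aa, alt_aa = alt_aa,
    wt_protein = wt_protein, mutant_protein = mutant_protein,
    vaf = if ("vaf" %in% names(variant)) variant$vaf else NA_real_,
    variant_key = if (class %in% c("none")) NA_character_
                  else make_variant_key(gene, aa_pos, ref_aa, alt_aa)
  )
}

annotate_one <- function(variant, model) {
  wt <- model$protein_seq
  mut_spliced <- apply_edit_to_cds(model, variant)
  if (is.null(mut_spliced)) {
    return(consequence_row(variant, model$gene_symbol, model$transcript_id,
                           class = "none"))
  }
  mut_protein <- translate_dna_biostrings(mut_spliced, to_first_stop = TRUE)
  len_delta <- nchar(variant$alt_allele) - nchar(variant$ref_allele)

  if (len_delta == 0L && nchar(variant$ref_allele) == 1L) {
    # SNV: locate the affected codon directly
    p <- first_difference(wt, mut_protein)
    if (is.na(p)) {
      # synonymous: recover the codon index from the coding position
      cds_pos <- coding_position(model, variant$pos)
      aa_pos <- (cds_pos - 1L) %/% 3L + 1L
      res <- substring(wt, aa_pos, aa_pos)
      return(consequence_row(variant, model$gene_symbol, model$transcript_id,
                             "synonymous", aa_pos, res, res, wt, wt))
    }
    if (p > nchar(wt)) {
      # substitution in the stop codon (stop-lost): not a vaccine target here
      return(consequence_row(variant, model$gene_symbol, model$transcript_id,
                             class = "none"))
    }
    ref_aa <- substring(wt, p, p)
    if (nchar(mut_protein) < p) {
      return(consequence_row(variant, model$gene_symbol, model$transcript_id,
                             "stop_gain", p, ref_aa, NA_character_,
                             wt, mut_protein))
    }
    alt_aa <- substring(mut_protein, p, p)
    return(consequence_row(variant, model$gene_symbol, model$transcript_id,
                           "missense", p, ref_aa, alt_aa, wt, mut_protein))
  }

  # indel
  class <- if (abs(len_delta) %% 3L == 0L) "inframe_indel" else "frameshift"
  p <- first_difference(wt, mut_protein)
  if (is.na(p)) p <- min(nchar(wt), nchar(mut_protein)) + 1L
  p <- min(p, nchar(mut_protein))
  if (p < 1L || nchar(mut_protein) == 0L) {
    return(consequence_row(variant, model$gene_symbol, model$transcript_id,
                           "stop_gain", 1L, substring(wt, 1L, 1L),
                           NA_character_, wt, mut_protein))
  }
  ref_aa <- if (p <= nchar(wt)) substring(wt, p, p) else NA_character_
  consequence_row(variant, model$gene_symbol, model$transcript_id,
                  class, p, ref_aa, NA_character_, wt, mut_protein)
}

# Apply the (anchored, normalized) edit to the genomic sequence of the CDS
# interval containing it, then splice and orient the mutant CDS.
apply_edit_to_cds <- function(model, variant) {
  cds <- model$cds[[1]]
  span_end <- variant$pos + nchar(variant$ref_allele) - 1L
  idx <- which(cds$start <= variant$pos & span_end <= cds$end)
  if (length(idx) != 1L) return(NULL)
  seg <- cds$seq[idx]
  off <- variant$pos - cds$start[idx] + 1L
  ref_len <- nchar(variant$ref_allele)
  observed <- substring(seg, off, off + ref_len - 1L)
  if (toupper(observed) != toupper(variant$ref_allele)) {
    abort(paste0("Reference mismatch at ", variant$chrom, ":", variant$pos,
                 ": VCF says ", variant$ref_allele, ", model has ", observed,
                 " (transcript ", model$transcript_id, ")."))
  }
  mutated <- paste0(
    substring(seg, 1L, off - 1L),
    variant$alt_allele,
    substring(seg, off + ref_len)
  )
  seqs <- cds$seq
  seqs[idx] <- mutated
  spliced <- paste(seqs, collapse = "")
  if (model$strand == "-") {
    spliced <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(spliced)))
  }
  spliced
}

translate_dna_biostrings <- function(dna, to_first_stop = TRUE) {
  n <- (nchar(dna) %/% 3L) * 3L
  if (n < 3L) return("")
  aa <- as.character(suppressWarnings(Biostrings::translate(
    Biostrings::DNAString(substring(dna, 1L, n)),
    if.fuzzy.codon = "X")))
  if (to_first_stop) sub("\\*.*$", "", aa) else aa
}

first_difference <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n > 0) {
    av <- utf8ToInt(substring(a, 1L, n))
    bv <- utf8ToInt(substring(b, 1L, n))
    d <- which(av != bv)
    if (length(d)) return(d[1])
  }
  if (nchar(a) != nchar(b)) return(n + 1L)
  NA_integer_
}

# 1-based position within the spliced CDS, in coding orientation.
coding_position <- function(model, genomic_pos) {
  cds <- model$cds[[1]]
  lens <- cds$end - cds$start + 1L
  idx <- which(cds$start <= genomic_pos & genomic_pos <= cds$end)
  stopifnot(length(idx) == 1L)
  fwd <- sum(lens[seq_len(idx - 1L)]) + (genomic_pos - cds$start[idx] + 1L)
  if (model$strand == "+") fwd else sum(lens) - fwd + 1L
}

#' Canonical gene-level variant key
#'
#' @param gene_symbol,aa_pos,ref_aa,alt_aa Components of the key.
#' @return `"GENE:pos:REF/ALT"`, case-normalized (gene upper-cased), stable
#'   across transcripts of the same gene.
#' @examples
#' make_variant_key("H2", 14, "H", "Y")   # "H2:14:H/Y"
#' @export
make_variant_key <- function(gene_symbol, aa_pos, ref_aa, alt_aa) {
  paste0(toupper(gene_symbol), ":", aa_pos, ":",
         toupper(ref_aa), "/", toupper(alt_aa))
}

#' Enumerate mutant epitopes with wild-type partners
#'
#' For every annotated consequence, extracts all k-mers (default 8-11, the
#' MHC class I length range) of the mutant protein that contain mutated
#' sequence. For missense variants each window covers the substituted
#' residue and is paired with the same-coordinate wild-type window (the two
#' differ at exactly `peptide_position`). For frameshifts and in-frame
#' indels every window overlapping the novel sequence (through the first
#' stop) is emitted with no wild-type partner. Synonymous and stop-gain
#' consequences yield no epitopes.
#'
#' @param consequences Tibble from [annotate_variants()].
#' @param lengths Integer vector of peptide lengths.
#' @return A tibble with columns `variant_key`, `gene_symbol`, `length`,
#'   `mut_peptide`, `wt_peptide`, `peptide_position` (1-based index of the
#'   first mutated residue within the peptide), plus carried-through `vaf`,
#'   `aa_pos`, `ref_aa`, `alt_aa`, `consequence_class`.
#' @export
enumerate_epitopes <- function(consequences, lengths = 8:11) {
  stopifnot(all(lengths >= 1))
  cons <- consequences %>%
    filter(.data$consequence_class %in% c("missense", "frameshift",
                                          "inframe_indel"))
  purrr::map_dfr(seq_len(nrow(cons)), function(i) {
    r <- cons[i, ]
    mut <- r$mutant_protein
    lm <- nchar(mut)
    windows <- purrr::map_dfr(sort(unique(as.integer(lengths))), function(k) {
      if (r$consequence_class == "missense") {
        starts <- seq2(max(1L, r$aa_pos - k + 1L), min(r$aa_pos, lm - k + 1L))
      } else {
        starts <- seq2(max(1L, r$aa_pos - k + 1L), lm - k + 1L)
      }
      if (length(starts) == 0) return(NULL)
      tibble(
        variant_key = r$variant_key,
        gene_symbol = r$gene_symbol,
        length = k,
        mut_peptide = substring(mut, starts, starts + k - 1L),
        wt_peptide = if (r$consequence_class == "missense")
          substring(r$wt_protein, starts, starts + k - 1L)
          else NA_character_,
        peptide_position = pmax(1L, r$aa_pos - starts + 1L),
        vaf = r$vaf, aa_pos = r$aa_pos,
        ref_aa = r$ref_aa, alt_aa = r$alt_aa,
        consequence_class = r$consequence_class
      )
    })
    if (nrow(windows) == 0) return(NULL)   # mutant protein shorter than any window
    distinct(windows, .data$mut_peptide, .data$peptide_position,
             .keep_all = TRUE)
  })
}

seq2 <- function(from, to) if (from > to) integer(0) else seq.int(from, to)

#' Design a mutation-centered long vaccine peptide
#'
#' Extracts a 27- or 31-residue window of the mutant protein around the
#' mutated residue. In a full-length window the mutation sits at the central
#' index (16 of 31, 14 of 27). Near a protein terminus the window slides
#' (rather than shrinks) to keep its full length, so the mutation index
#' moves off-center; only when the protein itself is shorter than the
#' window is the whole protein returned with `truncated = TRUE`.
#'
#' @param consequences Tibble from [annotate_variants()]; rows with classes
#'   other than `missense` and `inframe_indel` are dropped.
#' @param window Window length, 27 or 31 residues.
#' @return The input rows with added columns `augmented_peptide`,
#'   `mutation_index` (1-based index of the mutated residue within the
#'   peptide) and `truncated`.
#' @export
design_long_peptides <- function(consequences, window = 31) {
  if (!window %in% c(27L, 31L)) {
    abort("`window` must be 27 or 31 (synthesized long-peptide lengths).")
  }
  cons <- consequences %>%
    filter(.data$consequence_class %in% c("missense", "inframe_indel"))
  res <- purrr::map_dfr(seq_len(nrow(cons)), function(i) {
    r <- cons[i, ]
    d <- design_one_long_peptide(r$mutant_protein, r$aa_pos, window)
    bind_cols(r, tibble(augmented_peptide = d$peptide,
                        mutation_index = d$index,
                        truncated = d$truncated))
  })
  # the designed peptide must show the ALT residue at the designed index
  miss <- res$consequence_class == "missense"
  at_idx <- substring(res$augmented_peptide, res$mutation_index,
                      res$mutation_index)
  stopifnot(all(at_idx[miss] == res$alt_aa[miss]))
  res
}

design_one_long_peptide <- function(protein, aa_pos, window) {
  L <- nchar(protein)
  if (L < 8L) abort("Protein shorter than 8 residues; cannot design peptide.")
  center <- (window + 1L) %/% 2L   # 16 for 31-mers, 14 for 27-mers
  if (L < window) {
    return(list(peptide = protein, index = aa_pos, truncated = TRUE))
  }
  start <- aa_pos - (center - 1L)
  start <- max(1L, min(start, L - window + 1L))
  list(
    peptide = substring(protein, start, start + window - 1L),
    index = aa_pos - start + 1L,
    truncated = FALSE
  )
}
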