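#' Configuration for a synthetic tumor cohort
#'
#' Parameters of the seeded generator that stands in for a sequenced tumor:
#' a small genome of single-gene contigs with protein-coding transcript
#' models, somatic variants with realistic depth/VAF structure, and a
#' gene-expression table. Defaults emulate a deeply sequenced tumor cell
#' line: tumor depth negative-binomial around 120x (dispersion 8), normal
#' depth around 60x, VAF ~ Beta(2, 2) (cell-line somatic VAFs are high),
#' TPM log-normal (meanlog 1, sdlog 1.5), 80% of variants missense.
#'
#' @param n_genes Number of genes (one per contig).
#' @param n_variants Number of somatic variants to plant.
#' @param vaf_shape1,vaf_shape2 Beta parameters of the VAF distribution.
#' @param dp_mean,dp_dispersion Tumor-depth negative binomial (mean, size).
#' @param normal_dp_mean Mean normal depth (same dispersion).
#' @param tpm_meanlog,tpm_sdlog Log-normal TPM parameters.
#' @param fraction_missense Fraction of variants planted as missense SNVs;
#'   the remainder is split between synonymous SNVs and 1-bp frameshift
#'   deletions.
#' @param fraction_unexpressed Fraction of genes left out of the expression
#'   table (exercises the NO_EXPRESSION rule).
#' @param protein_length_range Range of protein lengths (residues).
#' @param multi_exon If `TRUE`, a third of the genes get 2-3 CDS exons.
#' @param reverse_strand If `TRUE`, a third of the genes are minus-strand.
#' @param seed Integer RNG seed; the bundle is a pure function of the
#'   configuration.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_genes = 60, n_variants = 150,
                          vaf_shape1 = 2, vaf_shape2 = 2,
                          dp_mean = 120, dp_dispersion = 8,
                          normal_dp_mean = 60,
                          tpm_meanlog = 1, tpm_sdlog = 1.5,
                          fraction_missense = 0.8,
                          fraction_unexpressed = 0.05,
                          protein_length_range = c(80L, 250L),
                          multi_exon = FALSE, reverse_strand = FALSE,
                          seed = 1L) {
  cfg <- as.list(environment())
  if (n_genes <= 0 || n_variants <= 0) abort("Counts must be positive.")
  if (fraction_missense < 0 || fraction_missense > 1) {
    abort("fraction_missense must lie in [0, 1].")
  }
  structure(cfg, class = "cohort_config")
}

#' Generate a synthetic cohort bundle
#'
#' Writes `genome.fa`, `models.gff3`, `variants.vcf` (VCF v4.2, samples
#' TUMOR and NORMAL with `GT:DP:AD`, INFO `SOR` and `MBQ`),
#' `expression.tsv`, and `truth.tsv` into `dir`. The truth table records,
#' for every planted variant, its realized depths/VAF/quality metrics, its
#' protein consequence derived independently of the annotation code path
#' (a straight codon-table translation at generation time), and the
#' expected outcome of every filtering rule, enabling exact end-to-end
#' assertions. Given the same configuration the bundle is byte-identical
#' across runs and platforms.
#'
#' @param config A [cohort_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the file `paths` and the in-memory
#'   `models`, `variants`, `expression`, `truth` tables.
#' @export
generate_cohort <- function(config = cohort_config(), dir) {
  stopifnot(inherits(config, "cohort_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  old_seed <- .Random.seed_exists()
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(config$seed)

  genes <- generate_genes(config)
  total_cds <- sum(vapply(genes, function(g) nchar(g$cds_seq), numeric(1)))
  if (config$n_variants > total_cds / 10) {
    abort("Configuration plants more variants than the CDS space supports.")
  }
  expression <- generate_expression(genes, config)
  variants <- generate_variants(genes, config)
  truth <- build_truth(variants, genes, expression, config)

  paths <- list(
    genome = file.path(dir, "genome.fa"),
    gff3 = file.path(dir, "models.gff3"),
    vcf = file.path(dir, "variants.vcf"),
    expression = file.path(dir, "expression.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_genome_fasta(genes, paths$genome)
  write_models_gff3(genes, paths$gff3)
  write_cohort_vcf(variants, paths$vcf)
  readr::write_tsv(expression, paths$expression, progress = FALSE)
  readr::write_tsv(truth, paths$truth, progress = FALSE)
  invisible(list(paths = paths, genes = genes, variants = variants,
                 expression = expression, truth = truth))
}

NON_STOP_CODONS <- names(CODON_TABLE)[CODON_TABLE != "*"]
STOP_CODONS <- names(CODON_TABLE)[CODON_TABLE == "*"]

generate_genes <- function(cfg) {
  lapply(seq_len(cfg$n_genes), function(g) {
    L <- sample(seq(cfg$protein_length_range[1], cfg$protein_length_range[2]), 1)
    codons <- c("ATG", sample(NON_STOP_CODONS, L - 1L, replace = TRUE),
                sample(STOP_CODONS, 1))
    cds_seq <- paste(codons, collapse = "")
    strand <- if (cfg$reverse_strand && g %% 3 == 0) "-" else "+"
    n_exon <- if (cfg$multi_exon && g %% 3 == 1) sample(2:3, 1) else 1L
    flank5 <- random_dna(50)
    # split the CDS (in coding orientation) into exons at codon-agnostic
    # breakpoints, then lay intervals on the contig with introns between
    len <- nchar(cds_seq)
    if (n_exon > 1L) {
      cuts <- sort(sample(seq_len(len - 1L), n_exon - 1L))
      pieces <- substring(cds_seq, c(1L, cuts + 1L), c(cuts, len))
    } else {
      pieces <- cds_seq
    }
    genomic_pieces <- if (strand == "-") {
      vapply(rev(pieces), reverse_complement, character(1))
    } else pieces
    introns <- replicate(length(pieces) - 1L, random_dna(sample(40:80, 1)))
    contig_parts <- character(0)
    intervals <- tibble(start = integer(0), end = integer(0))
    pos <- nchar(flank5)
    contig_parts <- flank5
    for (i in seq_along(genomic_pieces)) {
      s <- pos + 1L
      e <- pos + nchar(genomic_pieces[i])
      intervals <- bind_rows(intervals, tibble(start = s, end = e))
      contig_parts <- c(contig_parts, genomic_pieces[i])
      pos <- e
      if (i < length(genomic_pieces)) {
        contig_parts <- c(contig_parts, introns[i])
        pos <- pos + nchar(introns[i])
      }
    }
    contig <- paste(c(contig_parts, random_dna(50)), collapse = "")
    list(
      gene_symbol = sprintf("GENE%03d", g),
      transcript_id = sprintf("T%03d", g),
      chrom = sprintf("ctg%03d", g),
      strand = strand,
      contig = contig,
      intervals = intervals,
      cds_seq = cds_seq,                      # coding orientation, with stop
      protein = translate_dna(cds_seq, to_first_stop = TRUE)
    )
  })
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

generate_expression <- function(genes, cfg) {
  n <- length(genes)
  n_hidden <- floor(cfg$fraction_unexpressed * n)
  hidden <- if (n_hidden > 0) sample(n, n_hidden) else integer(0)
  tpm <- round(rlnorm(n, cfg$tpm_meanlog, cfg$tpm_sdlog), 3)
  tibble(
    gene_id = vapply(genes, `[[`, character(1), "gene_symbol"),
    gene_symbol = vapply(genes, `[[`, character(1), "gene_symbol"),
    tpm = tpm
  )[setdiff(seq_len(n), hidden), ]
}

# Plant one variant: pick a gene, a CDS coding position (outside start/stop
# codons), and an edit achieving the requested consequence class.
generate_variants <- function(genes, cfg) {
  n <- cfg$n_variants
  classes <- sample(
    c("missense", "synonymous", "frameshift"), n, replace = TRUE,
    prob = c(cfg$fraction_missense,
             (1 - cfg$fraction_missense) * 0.6,
             (1 - cfg$fraction_missense) * 0.4)
  )
  used <- new.env(parent = emptyenv())
  purrr::map_dfr(seq_len(n), function(i) {
    for (attempt in 1:200) {
      g <- genes[[sample(length(genes), 1)]]
      v <- try(plant_variant(g, classes[i]), silent = TRUE)
      if (inherits(v, "try-error") || is.null(v)) next
      key <- paste0(v$chrom, ":", v$pos, ":", v$ref_allele, ":", v$alt_allele)
      if (!is.null(used[[key]])) next
      used[[key]] <- TRUE
      return(bind_cols(v, plant_metrics(cfg)))
    }
    abort("Could not place a variant after 200 attempts; CDS space too small.")
  })
}

plant_variant <- function(g, class) {
  len <- nchar(g$cds_seq)
  prot_len <- nchar(g$protein)
  if (class == "frameshift") {
    # 1-bp deletion inside the coding region (not in start/stop codon)
    cpos <- sample(seq(4L, len - 6L), 1)
    gen <- coding_to_genomic(g, cpos)
    anchor_gen <- coding_to_genomic(g, cpos - 1L)
    # anchored deletion needs anchor immediately left on the genome
    if (g$strand == "+") {
      if (anchor_gen != gen - 1L) return(NULL)   # exon boundary
      ref <- substr_contig(g, gen - 1L, gen)
      alt <- substring(ref, 1L, 1L)
      pos <- gen - 1L
    } else {
      nxt <- coding_to_genomic(g, cpos + 1L)
      if (nxt != gen - 1L) return(NULL)
      ref <- substr_contig(g, gen - 1L, gen)
      alt <- substring(ref, 1L, 1L)
      pos <- gen - 1L
    }
    return(tibble(chrom = g$chrom, pos = pos, ref_allele = ref,
                  alt_allele = alt, variant_class = "deletion",
                  planted_class = "frameshift"))
  }
  # SNV inside an internal codon
  aa_pos <- sample(seq(2L, prot_len), 1)
  codon <- substring(g$cds_seq, 3L * aa_pos - 2L, 3L * aa_pos)
  within <- sample(1:3, 1)
  old_base <- substring(codon, within, within)
  for (b in sample(setdiff(c("A", "C", "G", "T"), old_base))) {
    new_codon <- codon
    substring(new_codon, within, within) <- b
    old_aa <- CODON_TABLE[[codon]]
    new_aa <- CODON_TABLE[[new_codon]]
    ok <- switch(class,
      missense = new_aa != old_aa && new_aa != "*",
      synonymous = new_aa == old_aa
    )
    if (isTRUE(ok)) {
      cpos <- 3L * (aa_pos - 1L) + within
      gen <- coding_to_genomic(g, cpos)
      ref <- if (g$strand == "+") old_base else reverse_complement(old_base)
      alt <- if (g$strand == "+") b else reverse_complement(b)
      return(tibble(chrom = g$chrom, pos = gen, ref_allele = ref,
                    alt_allele = alt, variant_class = "SNV",
                    planted_class = class))
    }
  }
  NULL
}

plant_metrics <- function(cfg) {
  tumor_dp <- max(1L, rnbinom(1, mu = cfg$dp_mean, size = cfg$dp_dispersion))
  vaf_target <- rbeta(1, cfg$vaf_shape1, cfg$vaf_shape2)
  tumor_ad <- max(1L, min(tumor_dp, round(vaf_target * tumor_dp)))
  normal_dp <- max(1L, rnbinom(1, mu = cfg$normal_dp_mean,
                               size = cfg$dp_dispersion))
  normal_ad_ref <- rbinom(1, normal_dp, 0.98)
  tibble(
    tumor_dp = as.integer(tumor_dp),
    tumor_ad_alt = as.integer(tumor_ad),
    normal_dp = as.integer(normal_dp),
    normal_ad_ref = as.integer(normal_ad_ref),
    base_quality = round(runif(1, 12, 40), 1),
    sor = round(stats::rgamma(1, shape = 2, scale = 1.2), 3),
    vaf = tumor_ad / tumor_dp
  )
}

# Genomic position of the i-th coding base (coding orientation).
coding_to_genomic <- function(g, cpos) {
  iv <- g$intervals
  lens <- iv$end - iv$start + 1L
  if (g$strand == "+") {
    cum <- cumsum(lens)
    k <- which(cpos <= cum)[1]
    before <- if (k > 1L) cum[k - 1L] else 0L
    iv$start[k] + (cpos - before - 1L)
  } else {
    # coding order runs through genomic intervals from last to first
    rlens <- rev(lens)
    cum <- cumsum(rlens)
    k <- which(cpos <= cum)[1]
    before <- if (k > 1L) cum[k - 1L] else 0L
    ridx <- nrow(iv) - k + 1L
    iv$end[ridx] - (cpos - before - 1L)
  }
}

substr_contig <- function(g, from, to) substring(g$contig, from, to)

# Independent consequence truth: re-derive the protein change with the
# plain codon-table translator (not the annotation code path).
build_truth <- function(variants, genes, expression, cfg) {
  gmap <- setNames(genes, vapply(genes, `[[`, character(1), "chrom"))
  th <- filter_thresholds()
  tpm_of <- setNames(expression$tpm, expression$gene_symbol)
  purrr::map_dfr(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    g <- gmap[[v$chrom]]
    mut_contig <- paste0(
      substring(g$contig, 1L, v$pos - 1L),
      v$alt_allele,
      substring(g$contig, v$pos + nchar(v$ref_allele))
    )
    shift <- nchar(v$alt_allele) - nchar(v$ref_allele)
    iv <- g$intervals
    # shift intervals right of the edit
    iv2 <- mutate(iv,
                  start = ifelse(.data$start > v$pos, .data$start + shift, .data$start),
                  end = ifelse(.data$end >= v$pos + nchar(v$ref_allele) - 1L,
                               .data$end + shift, .data$end))
    pieces <- vapply(seq_len(nrow(iv2)), function(k) {
      substring(mut_contig, iv2$start[k], iv2$end[k])
    }, character(1))
    spliced <- paste(pieces, collapse = "")
    if (g$strand == "-") spliced <- reverse_complement(spliced)
    mut_protein <- translate_dna(spliced, to_first_stop = TRUE)
    wt <- g$protein
    p <- first_difference(wt, mut_protein)
    class <- if (is.na(p)) "synonymous"
             else if (v$variant_class != "SNV") "frameshift"
             else if (nchar(mut_protein) < p) "stop_gain"
             else "missense"
    aa_pos <- if (is.na(p)) NA_integer_ else as.integer(min(p, nchar(mut_protein)))
    tpm <- unname(tpm_of[g$gene_symbol])
    fails <- c(
      TUMOR_DP = v$tumor_dp < th$tumor_dp_min,
      NORMAL_DP = v$normal_dp < th$normal_dp_min,
      TUMOR_AD = v$tumor_ad_alt < th$tumor_ad_min,
      NORMAL_AD = v$normal_ad_ref < th$normal_ad_min,
      BASEQ = v$base_quality < th$base_quality_min,
      SOR = v$sor > th$sor_max,
      VAF = v$vaf < th$vaf_min,
      TPM = !is.na(tpm) && tpm < th$tpm_min,
      NO_EXPRESSION = is.na(tpm)
    )
    tibble(
      variant_key = paste0(v$chrom, ":", v$pos, ":", v$ref_allele, ":",
                           v$alt_allele),
      gene_symbol = g$gene_symbol,
      planted_class = v$planted_class,
      truth_class = class,
      aa_pos = aa_pos,
      ref_aa = if (!is.na(p) && p <= nchar(wt)) substring(wt, p, p) else NA_character_,
      alt_aa = if (class == "missense") substring(mut_protein, p, p) else NA_character_,
      expect_pass = !any(fails),
      failed_rules = paste(names(fails)[fails], collapse = ",")
    )
  })
}

write_genome_fasta <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (g in genes) {
    writeLines(paste0(">", g$chrom), con)
    seq <- g$contig
    starts <- seq(1L, nchar(seq), by = 70L)
    writeLines(substring(seq, starts, pmin(starts + 69L, nchar(seq))), con)
  }
  invisible(path)
}

write_models_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in genes) {
    iv <- g$intervals
    # CDS phase in coding order
    lens <- iv$end - iv$start + 1L
    order_idx <- if (g$strand == "+") seq_len(nrow(iv)) else rev(seq_len(nrow(iv)))
    phase <- integer(nrow(iv))
    acc <- 0L
    for (k in order_idx) {
      phase[k] <- (3L - acc %% 3L) %% 3L
      acc <- acc + lens[k]
    }
    writeLines(sprintf(
      "%s\trnaneo\tgene\t%d\t%d\t.\t%s\t.\tID=gene:%s;gene_name=%s",
      g$chrom, min(iv$start), max(iv$end), g$strand, g$gene_symbol,
      g$gene_symbol), con)
    writeLines(sprintf(
      "%s\trnaneo\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=gene:%s;gene_name=%s",
      g$chrom, min(iv$start), max(iv$end), g$strand, g$transcript_id,
      g$gene_symbol, g$gene_symbol), con)
    for (k in seq_len(nrow(iv))) {
      writeLines(sprintf(
        "%s\trnaneo\tCDS\t%d\t%d\t.\t%s\t%d\tID=cds:%s.%d;Parent=%s;gene_name=%s",
        g$chrom, iv$start[k], iv$end[k], g$strand, phase[k],
        g$transcript_id, k, g$transcript_id, g$gene_symbol), con)
    }
  }
  invisible(path)
}

write_cohort_vcf <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=rnaneo-synthetic-cohort",
    "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"Strand odds ratio\">",
    "##INFO=<ID=MBQ,Number=1,Type=Float,Description=\"Median base quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR\tNORMAL"
  ), con)
  v <- arrange(variants, .data$chrom, .data$pos, .data$alt_allele)
  lines <- sprintf(
    "%s\t%d\t.\t%s\t%s\t.\t.\tSOR=%s;MBQ=%s\tGT:DP:AD\t0/1:%d:%d,%d\t0/0:%d:%d,%d",
    v$chrom, v$pos, v$ref_allele, v$alt_allele,
    format(v$sor, trim = TRUE), format(v$base_quality, trim = TRUE),
    v$tumor_dp, v$tumor_dp - v$tumor_ad_alt, v$tumor_ad_alt,
    v$normal_dp, v$normal_ad_ref, v$normal_dp - v$normal_ad_ref
  )
  writeLines(lines, con)
  invisible(path)
}
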