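# Shared fixtures and independent oracles, built in code at test time.

# --- tiny VCF writer ------------------------------------------------------
write_test_vcf <- function(path, rows,
                           samples = c("TUMOR", "NORMAL"),
                           info = TRUE) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"Strand odds ratio\">",
    "##INFO=<ID=MBQ,Number=1,Type=Float,Description=\"Median base quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(hdr, rows), path)
  path
}

# standard 3-variant VCF: one SNV with tumor AD=6/DP=60 (vaf 0.10)
simple_vcf <- function(path = tempfile(fileext = ".vcf")) {
  write_test_vcf(path, c(
    "chr1\t100\t.\tA\tG\t50\t.\tSOR=1.2;MBQ=33\tGT:DP:AD\t0/1:60:54,6\t0/0:40:40,0",
    "chr1\t200\t.\tC\tT\t60\t.\tSOR=0.8;MBQ=35\tGT:DP:AD\t0/1:80:60,20\t0/0:45:44,1",
    "chr2\t300\t.\tG\tGA\t40\t.\tSOR=2.0;MBQ=30\tGT:DP:AD\t0/1:70:55,15\t0/0:50:50,0"
  ))
}

write_tsv_file <- function(df, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(df, path, progress = FALSE)
  path
}

# --- straight-line filter oracle -----------------------------------------
# Independent re-implementation of the eight comparisons; deliberately a
# plain loop with if-statements, sharing no code with apply_filters().
filter_oracle <- function(variants, tpm_by_gene, genes, th = list(
    tumor_dp = 50, normal_dp = 30, tumor_ad = 5, normal_ad = 3,
    baseq = 20, sor = 5, vaf = 0.05, tpm = 1)) {
  out <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    fr <- character(0)
    if (!is.na(v$tumor_dp) && v$tumor_dp < th$tumor_dp) fr <- c(fr, "TUMOR_DP")
    if (!is.na(v$normal_dp) && v$normal_dp < th$normal_dp) fr <- c(fr, "NORMAL_DP")
    if (!is.na(v$tumor_ad_alt) && v$tumor_ad_alt < th$tumor_ad) fr <- c(fr, "TUMOR_AD")
    if (!is.na(v$normal_ad_ref) && v$normal_ad_ref < th$normal_ad) fr <- c(fr, "NORMAL_AD")
    if (!is.na(v$base_quality) && v$base_quality < th$baseq) fr <- c(fr, "BASEQ")
    if (!is.na(v$sor) && v$sor > th$sor) fr <- c(fr, "SOR")
    if (!is.na(v$vaf) && v$vaf < th$vaf) fr <- c(fr, "VAF")
    g <- genes[i]
    tpm <- tpm_by_gene[[g]]
    if (is.null(tpm) || is.na(tpm)) {
      fr <- c(fr, "NO_EXPRESSION")
    } else if (tpm < th$tpm) {
      fr <- c(fr, "TPM")
    }
    out[[i]] <- fr
  }
  out
}

# random variant tibble for filter property tests
random_variants <- function(n, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    chrom = paste0("chr", sample(1:5, n, TRUE)),
    pos = sample.int(1e6, n),
    ref_allele = sample(c("A", "C", "G", "T"), n, TRUE),
    alt_allele = sample(c("A", "C", "G", "T"), n, TRUE),
    tumor_dp = sample(0:150, n, TRUE),
    tumor_ad_alt = NA_integer_,
    normal_dp = sample(0:80, n, TRUE),
    normal_ad_ref = sample(0:60, n, TRUE),
    base_quality = round(runif(n, 5, 45), 1),
    sor = round(runif(n, 0, 9), 2),
    vaf = NA_real_
  ) |>
    dplyr::mutate(
      alt_allele = ifelse(alt_allele == ref_allele, "N", alt_allele),
      tumor_ad_alt = mapply(function(dp) if (dp == 0) 0L else sample(0:dp, 1),
                            tumor_dp),
      vaf = ifelse(tumor_dp > 0, tumor_ad_alt / tumor_dp, NA_real_)
    ))
}

# --- transcript-model fixture builder ------------------------------------
# Single-exon model on a synthetic contig: flank + CDS + flank.
make_test_model <- function(cds, gene = "TG1", transcript = "TX1",
                            chrom = "ctgT", strand = "+", flank = 20L) {
  stopifnot(nchar(cds) %% 3 == 0)
  left <- paste(rep("A", flank), collapse = "")
  genomic <- if (strand == "-") revcomp_chr(cds) else cds
  contig <- paste0(left, genomic, left)
  protein <- sub("\\*$", "", paste(
    seqinr::translate(strsplit(cds, NULL)[[1]]), collapse = ""))
  tibble::tibble(
    transcript_id = transcript, gene_symbol = gene, chrom = chrom,
    strand = strand,
    cds = list(tibble::tibble(start = flank + 1L,
                              end = flank + nchar(cds),
                              seq = genomic)),
    protein_seq = protein
  )
}

revcomp_chr <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, NULL)[[1]]), collapse = ""))
}

# random CDS of n_aa residues (ATG start, no internal stop, one stop)
random_cds <- function(n_aa, seed = NULL) {
  codons <- names(rnaneo:::CODON_TABLE)
  nonstop <- codons[rnaneo:::CODON_TABLE != "*"]
  stops <- codons[rnaneo:::CODON_TABLE == "*"]
  pick <- function() paste(
    c("ATG", sample(nonstop, n_aa - 1, TRUE), sample(stops, 1)),
    collapse = "")
  if (is.null(seed)) pick() else withr::with_seed(seed, pick())
}

# brute-force epitope window oracle: all k-mers of mut covering aa_pos
window_oracle <- function(mut_protein, aa_pos, lengths = 8:11) {
  res <- list()
  L <- nchar(mut_protein)
  for (k in lengths) {
    for (s in seq_len(max(0L, L - k + 1L))) {
      if (s <= aa_pos && aa_pos <= s + k - 1L) {
        res[[length(res) + 1]] <- c(substr(mut_protein, s, s + k - 1L),
                                    aa_pos - s + 1L)
      }
    }
  }
  res
}

# allele names appearing across the packaged candidate tables
table_alleles <- function() {
  c("H-2-Kd", "H-2-Dd", "H2-Ld", "H-2-Kb", "H-2-Db", "H-2-IAb",
    "HLA-A02:07", "HLA-B15:27", "HLA-B46:01", "HLA-C01:02",
    "DRB1_0901", "DRB1_1501", "HLA-DPA10202-DPB10202",
    "HLA-DQA10102-DQB10303", "HLA-DQA10303-DQB10602")
}
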