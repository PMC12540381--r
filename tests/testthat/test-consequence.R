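# Build a CDS whose residue 14 is H (CAT) so a C>T SNV gives H/Y.
cds_with_codon <- function(codon, aa_index, n_aa = 30, seed = 5) {
  cds <- random_cds(n_aa, seed = seed)
  substring(cds, 3 * aa_index - 2, 3 * aa_index) <- codon
  cds
}

snv_at <- function(model, cds_offset, ref, alt) {
  iv <- model$cds[[1]]
  tibble::tibble(
    chrom = model$chrom, pos = iv$start[1] + cds_offset - 1L,
    ref_allele = ref, alt_allele = alt, variant_class = "SNV",
    tumor_dp = 100L, tumor_ad_alt = 50L, normal_dp = 50L,
    normal_ad_ref = 50L, base_quality = 35, sor = 1, vaf = 0.5
  )
}

test_that("an SNV that changes CAT to TAT is annotated as missense H/Y", {
  cds <- cds_with_codon("CAT", 14)
  model <- make_test_model(cds)
  v <- snv_at(model, 3 * 14 - 2, "C", "T")
  cons <- annotate_variants(v, model)
  expect_equal(cons$consequence_class, "missense")
  expect_equal(cons$aa_pos, 14L)
  expect_equal(cons$ref_aa, "H")
  expect_equal(cons$alt_aa, "Y")
  expect_equal(substr(cons$mutant_protein, 14, 14), "Y")
  # mutant protein differs from wild type at exactly aa_pos
  diffs <- which(strsplit(cons$mutant_protein, NULL)[[1]] !=
                 strsplit(cons$wt_protein, NULL)[[1]])
  expect_equal(diffs, 14L)
  expect_equal(cons$variant_key, "TG1:14:H/Y")
})

test_that("a third-position SNV with identical translation is synonymous", {
  cds <- cds_with_codon("CTT", 10)   # Leu; CTT>CTC stays Leu
  model <- make_test_model(cds)
  v <- snv_at(model, 3 * 10, "T", "C")
  cons <- annotate_variants(v, model)
  expect_equal(cons$consequence_class, "synonymous")
  expect_equal(cons$aa_pos, 10L)
  expect_equal(cons$ref_aa, cons$alt_aa)
})

test_that("a single-base deletion causes a frameshift translated to the first stop", {
  cds <- random_cds(40, seed = 21)
  model <- make_test_model(cds)
  # anchored 1-bp deletion removing the first base of codon 10
  iv <- model$cds[[1]]
  del_pos <- iv$start[1] + (3 * 10 - 2) - 1L
  ref <- substr(cds, 3 * 10 - 3, 3 * 10 - 2)
  v <- snv_at(model, 0, ref, substr(ref, 1, 1))
  v$pos <- del_pos - 1L
  v$variant_class <- "deletion"
  cons <- annotate_variants(v, model)
  expect_equal(cons$consequence_class, "frameshift")
  # independent oracle: translate the edited CDS with seqinr
  mutated <- paste0(substr(cds, 1, 3 * 10 - 3), substr(cds, 3 * 10 - 1, nchar(cds)))
  aa <- seqinr::translate(strsplit(tolower(mutated), NULL)[[1]])
  expected <- paste(aa[seq_len(which(aa == "*")[1] - 1)], collapse = "")
  expect_equal(cons$mutant_protein, expected)
})

test_that("reverse-strand transcripts are annotated via the reverse complement", {
  cds <- cds_with_codon("CAT", 14, seed = 31)
  model <- make_test_model(cds, strand = "-")
  # genomic position of the coding C of codon 14 on the minus strand
  iv <- model$cds[[1]]
  cds_pos <- 3 * 14 - 2
  genomic <- iv$end[1] - cds_pos + 1L
  v <- snv_at(model, 1, "G", "A")   # revcomp of C>T
  v$pos <- genomic
  cons <- annotate_variants(v, model)
  expect_equal(cons$consequence_class, "missense")
  expect_equal(cons$aa_pos, 14L)
  expect_equal(cons$ref_aa, "H")
  expect_equal(cons$alt_aa, "Y")
})

test_that("variants outside any CDS yield a no-consequence row, not an error", {
  model <- make_test_model(random_cds(20, seed = 41))
  v <- snv_at(model, 1, "A", "G")
  v$pos <- 3L  # in the 5' flank
  cons <- annotate_variants(v, model)
  expect_equal(cons$consequence_class, "none")
  expect_true(is.na(cons$aa_pos))
})

test_that("annotation agrees with independent re-translation on random SNVs", {
  set.seed(77)
  for (rep in 1:60) {
    n_aa <- sample(25:60, 1)
    cds <- random_cds(n_aa)
    strand <- sample(c("+", "-"), 1)
    model <- make_test_model(cds, strand = strand)
    cds_pos <- sample(seq(4, 3 * n_aa), 1)  # skip the start codon
    old <- substr(cds, cds_pos, cds_pos)
    new <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    mutated_cds <- cds
    substring(mutated_cds, cds_pos, cds_pos) <- new
    aa <- seqinr::translate(strsplit(tolower(mutated_cds), NULL)[[1]])
    stop_at <- which(aa == "*")[1]
    oracle_protein <- paste(aa[seq_len(
      if (is.na(stop_at)) length(aa) else stop_at - 1)], collapse = "")

    iv <- make_test_model(cds, strand = strand)$cds[[1]]
    if (strand == "+") {
      pos <- iv$start[1] + cds_pos - 1L
      ref <- old; alt <- new
    } else {
      pos <- iv$end[1] - cds_pos + 1L
      ref <- revcomp_chr(old); alt <- revcomp_chr(new)
    }
    v <- snv_at(model, 1, ref, alt); v$pos <- pos
    cons <- annotate_variants(v, model)
    if (cons$consequence_class %in% c("missense", "synonymous")) {
      expect_equal(cons$mutant_protein, oracle_protein)
    } else if (cons$consequence_class == "stop_gain") {
      expect_equal(cons$mutant_protein, oracle_protein)
    }
  }
})

test_that("interior missense sites yield the closed-form 38 epitope pairs", {
  cds <- cds_with_codon("CAT", 20, n_aa = 45, seed = 51)
  model <- make_test_model(cds)
  v <- snv_at(model, 3 * 20 - 2, "C", "T")
  cons <- annotate_variants(v, model)
  ep <- enumerate_epitopes(cons, lengths = 8:11)
  expect_equal(nrow(ep), 38)   # 8 + 9 + 10 + 11 windows
  expect_equal(as.vector(table(ep$length)), c(8L, 9L, 10L, 11L))
  # every pair differs from its wild-type partner exactly at peptide_position
  for (i in seq_len(nrow(ep))) {
    d <- which(strsplit(ep$mut_peptide[i], NULL)[[1]] !=
               strsplit(ep$wt_peptide[i], NULL)[[1]])
    expect_equal(d, ep$peptide_position[i])
  }
})

test_that("epitopes at the protein start clip to one window per length", {
  cds <- cds_with_codon("CAT", 1, n_aa = 40, seed = 52)
  # mutate residue 1 (the start methionine is residue 1; use residue 2 to
  # keep a translatable protein, then residue-1 logic via position 2)
  model <- make_test_model(cds_with_codon("CAT", 2, n_aa = 40, seed = 52))
  v <- snv_at(model, 3 * 2 - 2, "C", "T")
  cons <- annotate_variants(v, model)
  ep <- enumerate_epitopes(cons, lengths = 8:11)
  # aa_pos = 2: windows starting at 1 or 2 -> 2 per length
  expect_equal(nrow(ep), 8)
  expect_true(all(ep$peptide_position %in% c(1L, 2L)))
})

test_that("epitope windows match brute-force enumeration on random fixtures", {
  set.seed(123)
  for (rep in 1:60) {
    n_aa <- sample(12:50, 1)
    aa_idx <- sample(2:n_aa, 1)
    cds <- cds_with_codon("CAT", aa_idx, n_aa = n_aa, seed = NULL)
    model <- make_test_model(cds)
    v <- snv_at(model, 3 * aa_idx - 2, "C", "T")
    cons <- annotate_variants(v, model)
    if (cons$consequence_class != "missense") next
    ep <- enumerate_epitopes(cons, lengths = 8:11)
    oracle <- window_oracle(cons$mutant_protein, cons$aa_pos, 8:11)
    expect_equal(nrow(ep), length(oracle))
    got <- paste(ep$mut_peptide, ep$peptide_position)
    want <- vapply(oracle, function(o) paste(o[1], o[2]), character(1))
    expect_setequal(got, want)
  }
})

test_that("frameshift epitopes cover the novel tail and carry no wild-type partner", {
  cds <- random_cds(40, seed = 61)
  model <- make_test_model(cds)
  iv <- model$cds[[1]]
  ref <- substr(cds, 3 * 10 - 3, 3 * 10 - 2)
  v <- snv_at(model, 1, ref, substr(ref, 1, 1))
  v$pos <- iv$start[1] + (3 * 10 - 3) - 1L
  v$variant_class <- "deletion"
  cons <- annotate_variants(v, model)
  expect_equal(cons$consequence_class, "frameshift")
  ep <- enumerate_epitopes(cons, lengths = 9)
  expect_true(all(is.na(ep$wt_peptide)))
  # every window overlaps the novel region starting at aa_pos
  expect_true(all(ep$peptide_position >= 1))
  lm <- nchar(cons$mutant_protein)
  n_windows <- max(0, (lm - 8) - max(1, cons$aa_pos - 8) + 1)
  expect_equal(nrow(ep), n_windows)
})

test_that("synonymous and stop-gain consequences yield no epitopes", {
  cds <- cds_with_codon("CTT", 10, seed = 71)
  model <- make_test_model(cds)
  v <- snv_at(model, 3 * 10, "T", "C")
  cons <- annotate_variants(v, model)
  expect_equal(nrow(enumerate_epitopes(cons)), 0)
})

test_that("long peptides are mutation-centered at index 16 of 31 and 14 of 27", {
  cds <- cds_with_codon("CAT", 60, n_aa = 120, seed = 81)
  model <- make_test_model(cds)
  v <- snv_at(model, 3 * 60 - 2, "C", "T")
  cons <- annotate_variants(v, model)
  for (win in c(31L, 27L)) {
    lp <- design_long_peptides(cons, window = win)
    expect_equal(nchar(lp$augmented_peptide), win)
    center <- (win + 1) %/% 2
    expect_equal(lp$mutation_index, center)
    expect_equal(substr(lp$augmented_peptide, center, center), "Y")
    expect_false(lp$truncated)
  }
})

test_that("windows slide (not shrink) at protein termini", {
  # mutation at residue 5 of a 100-residue protein: window = residues 1..31
  cds <- cds_with_codon("CAT", 5, n_aa = 100, seed = 82)
  model <- make_test_model(cds)
  v <- snv_at(model, 3 * 5 - 2, "C", "T")
  cons <- annotate_variants(v, model)
  lp <- design_long_peptides(cons, window = 31)
  expect_equal(nchar(lp$augmented_peptide), 31)
  expect_equal(lp$mutation_index, 5L)
  expect_equal(lp$augmented_peptide, substr(cons$mutant_protein, 1, 31))
  # C-terminal slide
  cds2 <- cds_with_codon("CAT", 97, n_aa = 100, seed = 83)
  model2 <- make_test_model(cds2)
  v2 <- snv_at(model2, 3 * 97 - 2, "C", "T")
  cons2 <- annotate_variants(v2, model2)
  lp2 <- design_long_peptides(cons2, window = 31)
  expect_equal(nchar(lp2$augmented_peptide), 31)
  expect_equal(lp2$mutation_index, 31L - (100L - 97L))
  # brute-force check of the slide rule across all positions
  for (aa_pos in c(1, 2, 16, 50, 85, 99, 100)) {
    got <- rnaneo:::design_one_long_peptide(cons$mutant_protein, aa_pos, 31)
    start <- max(1, min(aa_pos - 15, 100 - 30))
    expect_equal(got$peptide, substr(cons$mutant_protein, start, start + 30))
    expect_equal(got$index, aa_pos - start + 1)
  }
})

test_that("proteins shorter than the window are returned whole and flagged", {
  cds <- cds_with_codon("CAT", 10, n_aa = 20, seed = 84)
  model <- make_test_model(cds)
  v <- snv_at(model, 3 * 10 - 2, "C", "T")
  cons <- annotate_variants(v, model)
  lp <- design_long_peptides(cons, window = 31)
  expect_true(lp$truncated)
  expect_equal(nchar(lp$augmented_peptide), 20)
  expect_equal(lp$mutation_index, 10L)
  expect_error(design_long_peptides(cons, window = 25), "27 or 31")
})

test_that("variant keys are canonical, case-normalized and gene-level", {
  expect_equal(make_variant_key("H2", 14, "H", "Y"), "H2:14:H/Y")
  expect_equal(make_variant_key("atp10a", 9, "t", "m"), "ATP10A:9:T/M")
  # keys collide exactly when (gene, position, change) coincide
  set.seed(9)
  keys <- replicate(100, make_variant_key(
    sample(c("GA", "GB", "GC"), 1), sample(1:5, 1),
    sample(c("A", "H"), 1), sample(c("Y", "T"), 1)))
  tuples <- unique(keys)
  expect_equal(length(tuples), length(unique(tuples)))
})
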