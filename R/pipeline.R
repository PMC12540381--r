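#' Run the full RNA-only neoantigen pipeline
#'
#' Chains the pipeline stages on in-memory inputs: filter variants, annotate
#' protein consequences, enumerate 8-11-mer epitopes, predict binding,
#' collapse to the best epitope per variant, score, rank, and design the
#' long vaccine peptide for each selected candidate.
#'
#' @param variants Variant tibble (see [read_vcf()]).
#' @param models Transcript model tibble (see [read_transcript_models()]).
#' @param expression Expression tibble (see [read_expression()]).
#' @param alleles Character vector of typed MHC alleles.
#' @param predictor A `neo_predictor` for peptide-MHC binding.
#' @param thresholds A [filter_thresholds()] object.
#' @param weights A [scoring_weights()] object.
#' @param mode `"rna"` ranks every epitope of a passing variant by priority
#'   score; `"conventional"` first applies the strict IC50 < `cutoff_nm`
#'   candidate rule before ranking.
#' @param cutoff_nm IC50 candidate cutoff used in conventional mode.
#' @param top_n Number of candidates to select.
#' @param window Long-peptide window (27 or 31).
#' @param lengths Epitope lengths to enumerate.
#' @param id_prefix Prefix for assigned candidate ids (`M1`, `M2`, ...).
#' @return A list of class `neo_run` with elements `verdicts`, `summary`,
#'   `consequences`, `epitopes`, `scored`, `candidates` (the ranked top-N
#'   table in the candidate-TSV schema plus `variant_key`).
#' @export
run_pipeline <- function(variants, models, expression, alleles,
                         predictor = toy_predictor(),
                         thresholds = filter_thresholds(),
                         weights = scoring_weights(),
                         mode = c("rna", "conventional"),
                         cutoff_nm = 500, top_n = 10, window = 31,
                         lengths = 8:11, id_prefix = "M") {
  mode <- match.arg(mode)

  gene_of <- gene_for_variants(variants, models)
  verdicts <- apply_filters(variants, expression, gene_of, thresholds)
  passing <- as_tibble(variants)[verdicts$passed, ]

  consequences <- annotate_variants(passing, models)
  coding <- filter(consequences,
                   .data$consequence_class %in% c("missense", "frameshift",
                                                  "inframe_indel"))
  epitopes <- enumerate_epitopes(coding, lengths = lengths)
  scored <- score_epitopes(epitopes, alleles, predictor)
  if (mode == "conventional") {
    scored <- filter(scored, .data$mut_ic50 < cutoff_nm)
  }
  best <- best_epitope_per_variant(scored)

  tpm_of <- expression %>% select("gene_symbol", "tpm")
  joined <- best %>%
    left_join(tpm_of, by = "gene_symbol") %>%
    compute_subscores() %>%
    add_priority_score(weights)
  top <- rank_and_select(joined, n = top_n)

  long <- coding %>%
    filter(.data$variant_key %in% top$variant_key,
           .data$consequence_class %in% c("missense", "inframe_indel")) %>%
    design_long_peptides(window = window) %>%
    select("variant_key", "augmented_peptide", "mutation_index", "truncated")
  top <- left_join(top, long, by = "variant_key")

  candidates <- top %>%
    mutate(
      neoantigen_id = paste0(id_prefix, row_number()),
      hla_allele = .data$allele,
      allele_frequency = .data$vaf,
      amino_acid_change = paste0(.data$ref_aa, "/",
                                 if_else(is.na(.data$alt_aa), "fs",
                                         .data$alt_aa)),
      mut_mhc_ic50 = .data$mut_ic50,
      synthesis_failed = FALSE
    ) %>%
    select("neoantigen_id", "hla_allele", "allele_frequency",
           "amino_acid_change", "gene_symbol", "peptide_position",
           "mut_mhc_ic50", "priority_score", "augmented_peptide",
           "synthesis_failed", "variant_key")

  structure(
    list(verdicts = verdicts, summary = summarize_filtering(verdicts),
         consequences = consequences, epitopes = epitopes,
         scored = scored, candidates = candidates, mode = mode),
    class = "neo_run"
  )
}

#' @export
print.neo_run <- function(x, ...) {
  cat(sprintf("Neoantigen pipeline run (%s mode)\n", x$mode))
  print(x$summary)
  cat(sprintf("  %d coding consequences, %d epitopes, %d candidates selected\n",
              sum(x$consequences$consequence_class %in%
                    c("missense", "frameshift", "inframe_indel")),
              nrow(x$epitopes), nrow(x$candidates)))
  invisible(x)
}

#' Map variants to the gene symbol of the transcript model they overlap
#'
#' @param variants Variant tibble.
#' @param models Transcript model tibble.
#' @return Character vector of gene symbols (`NA` for intergenic variants),
#'   one per variant.
#' @export
gene_for_variants <- function(variants, models) {
  v <- as_tibble(variants)
  vapply(seq_len(nrow(v)), function(i) {
    hits <- overlapping_models(v[i, ], models)
    if (nrow(hits) == 0) NA_character_ else hits$gene_symbol[1]
  }, character(1))
}

#' Funnel plot of a filtering run
#'
#' @param summary A `neo_filter_summary` from [summarize_filtering()].
#' @return A ggplot object: per-rule failure counts next to the pass count.
#' @export
plot_filter_funnel <- function(summary) {
  stopifnot(inherits(summary, "neo_filter_summary"))
  df <- bind_rows(
    summary$per_rule %>% rename(n = "n_failed") %>% mutate(kind = "failed"),
    tibble(rule = "PASS", n = summary$n_pass, kind = "passed")
  )
  df$rule <- factor(df$rule, levels = c(FILTER_RULES, "PASS"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rule, y = .data$n,
                                   fill = .data$kind)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(failed = "#CC6677",
                                          passed = "#117733")) +
    ggplot2::labs(x = NULL, y = "variants", fill = NULL,
                  title = "Variant filtering funnel") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Priority-score landscape of candidates
#'
#' @param candidates Candidate tibble with `mut_mhc_ic50` and
#'   `priority_score` columns.
#' @return A ggplot object (IC50 on a log axis vs priority score).
#' @export
plot_priority <- function(candidates) {
  ggplot2::ggplot(candidates,
                  ggplot2::aes(x = .data$mut_mhc_ic50,
                               y = .data$priority_score)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "mutant IC50 (nM)", y = "priority score",
                  title = "Candidate priority landscape") +
    ggplot2::theme_minimal()
}
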