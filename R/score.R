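#' Weights for the multi-dimensional priority score
#'
#' The priority score combines five bounded sub-scores: predicted binding
#' (mutant IC50, optionally sharpened by the mutant/wild-type differential),
#' gene expression (TPM), variant allele frequency, DNA-RNA mutation
#' concordance, and antigen-presentation likelihood. Published candidate
#' tables from comparable screens do not disclose their weight vectors, so
#' the weights here are explicit configuration with an equal-weight default;
#' printed priority scores from other pipelines are not a validation target.
#'
#' @param binding,expression,vaf,concordance,presentation Non-negative
#'   weights.
#' @param normalize If `TRUE` (default) weights are rescaled to sum to 1.
#' @return An object of class `neo_weights`.
#' @export
scoring_weights <- function(binding = 1, expression = 1, vaf = 1,
                            concordance = 1, presentation = 1,
                            normalize = TRUE) {
  w <- c(binding = binding, expression = expression, vaf = vaf,
         concordance = concordance, presentation = presentation)
  if (any(!is.finite(w)) || any(w < 0)) {
    abort("Weights must be finite and non-negative.")
  }
  if (sum(w) == 0) abort("At least one scoring weight must be positive.")
  if (normalize) w <- w / sum(w)
  structure(list(w = w, normalized = normalize), class = "neo_weights")
}

#' @export
print.neo_weights <- function(x, ...) {
  cat("Priority-score weights", if (x$normalized) "(normalized)" else "", "\n")
  print(round(x$w, 4))
  invisible(x)
}

#' Bounded sub-scores for priority ranking
#'
#' Maps each candidate's raw measurements onto `[0, 1]`:
#'
#' * `s_binding`: `1 - log(mut_ic50)/log(50000)`, clamped to `[0, 1]` (IC50
#'   1 nM or stronger scores 1; 50000 nM scores 0). When `wt_ic50` is
#'   available the score is multiplied by a wild-type differential factor
#'   `(clamp(log10(wt_ic50 / mut_ic50), 0, 1) + wt_baseline) /
#'   (1 + wt_baseline)`, rewarding mutant-specific binders while keeping the
#'   result in `[0, 1]`.
#' * `s_expression`: `log1p(tpm) / (log1p(tpm) + log1p(tpm_half))`, a
#'   saturating map reaching 0.5 at `tpm_half` (default 10 TPM).
#' * `s_vaf`: the VAF itself.
#' * `s_concordance`: 1 when a matched DNA call supports the RNA variant;
#'   in RNA-only runs there is no DNA to compare, so it defaults to 1 for
#'   every candidate (a provenance note, not evidence).
#' * `s_presentation`: `1 - percent_rank/100` when the predictor reports a
#'   rank, else 0.5.
#'
#' @param records A tibble with columns `mut_ic50` (required, > 0) and
#'   optionally `wt_ic50`, `tpm`, `vaf`, `concordant`, `mut_rank`.
#' @param tpm_half TPM giving `s_expression = 0.5`.
#' @param wt_baseline Baseline of the wild-type differential factor.
#' @return `records` with the five `s_*` columns added.
#' @export
compute_subscores <- function(records, tpm_half = 10, wt_baseline = 0.5) {
  if (!"mut_ic50" %in% names(records)) abort("records need a mut_ic50 column.")
  if (any(records$mut_ic50 <= 0, na.rm = TRUE)) {
    abort("mut_ic50 must be positive (nM).")
  }
  clamp01 <- function(x) pmin(1, pmax(0, x))
  base <- clamp01(1 - log(records$mut_ic50) / log(50000))
  wt <- records[["wt_ic50"]] %||% rep(NA_real_, nrow(records))
  diff_factor <- ifelse(
    is.na(wt), 1,
    (clamp01(log10(wt / records$mut_ic50)) + wt_baseline) / (1 + wt_baseline)
  )
  tpm <- records[["tpm"]] %||% rep(NA_real_, nrow(records))
  rank <- records[["mut_rank"]] %||% rep(NA_real_, nrow(records))
  conc <- records[["concordant"]] %||% rep(TRUE, nrow(records))
  records %>%
    mutate(
      s_binding = base * diff_factor,
      s_expression = ifelse(is.na(tpm), 0,
                            log1p(tpm) / (log1p(tpm) + log1p(tpm_half))),
      s_vaf = ifelse(is.na(.data$vaf), 0, .data$vaf),
      s_concordance = as.numeric(conc),
      s_presentation = ifelse(is.na(rank), 0.5, 1 - rank / 100)
    )
}

#' Weighted priority score
#'
#' `100 * sum(w_i * s_i)` over the five sub-scores with normalized weights,
#' giving a deterministic score in `[0, 100]`.
#'
#' @param records A tibble carrying the `s_*` columns from
#'   [compute_subscores()].
#' @param weights A [scoring_weights()] object.
#' @return `records` with a `priority_score` column added.
#' @export
add_priority_score <- function(records, weights = scoring_weights()) {
  stopifnot(inherits(weights, "neo_weights"))
  w <- weights$w / sum(weights$w)
  records %>%
    mutate(priority_score = 100 * (
      w[["binding"]] * .data$s_binding +
      w[["expression"]] * .data$s_expression +
      w[["vaf"]] * .data$s_vaf +
      w[["concordance"]] * .data$s_concordance +
      w[["presentation"]] * .data$s_presentation
    ))
}

#' Per-variant best epitope
#'
#' Collapses scored epitopes to one row per variant: the epitope with the
#' lowest mutant IC50 across all lengths and alleles (ties broken by
#' peptide then allele, alphabetically, for determinism).
#'
#' @param scored Tibble from [score_epitopes()].
#' @return One row per `variant_key`.
#' @export
best_epitope_per_variant <- function(scored) {
  scored %>%
    group_by(.data$variant_key) %>%
    arrange(.data$mut_ic50, .data$mut_peptide, .data$allele,
            .by_group = TRUE) %>%
    slice_head(n = 1) %>%
    ungroup()
}

#' Rank candidates and select the top N
#'
#' Orders by descending priority score; ties are broken by lower mutant
#' IC50, then higher TPM, then gene symbol, then variant key, so the
#' selection is deterministic and stable under permutation of the input.
#'
#' @param records Scored candidate tibble (needs `priority_score`; tie
#'   columns `mut_ic50`, `tpm`, `gene_symbol`, `variant_key` used when
#'   present).
#' @param n Number of candidates to keep.
#' @return The top `min(n, nrow(records))` rows, in rank order.
#' @export
rank_and_select <- function(records, n = 10) {
  if (!is.numeric(n) || length(n) != 1 || n <= 0) {
    abort("`n` must be a positive integer.")
  }
  fill <- function(col, default) records[[col]] %||% rep(default, nrow(records))
  ord <- order(
    -records$priority_score,
    fill("mut_ic50", Inf),
    -rank_numeric(fill("tpm", -Inf)),
    fill("gene_symbol", ""),
    fill("variant_key", ""),
    method = "radix"
  )
  records[ord, ][seq_len(min(n, nrow(records))), ]
}

rank_numeric <- function(x) {
  x[is.na(x)] <- -Inf
  x
}

#' Flag synthesis failures and count synthesizable candidates
#'
#' Long peptides can fail chemical synthesis (hydrophobic stretches,
#' aggregation); such candidates stay in the table but are excluded from
#' the synthesized count and from vaccine export.
#'
#' @param records Candidate tibble with a `neoantigen_id` column.
#' @param failed_ids Character vector of ids that failed synthesis.
#' @return `records` with a logical `synthesis_failed` column; the number
#'   of synthesizable candidates is attached as attribute `n_synthesized`
#'   and returned by [n_synthesized()].
#' @export
mark_synthesis_failures <- function(records, failed_ids = character(0)) {
  unknown <- setdiff(failed_ids, records$neoantigen_id)
  if (length(unknown)) {
    warn(paste0("Synthesis-failure flag for unknown id(s): ",
                paste(unknown, collapse = ", ")))
  }
  out <- records %>%
    mutate(synthesis_failed = .data$neoantigen_id %in% failed_ids)
  attr(out, "n_synthesized") <- sum(!out$synthesis_failed)
  out
}

#' @rdname mark_synthesis_failures
#' @export
n_synthesized <- function(records) {
  stopifnot("synthesis_failed" %in% names(records))
  sum(!records$synthesis_failed)
}
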