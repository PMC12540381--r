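#' Overlap between two candidate sets
#'
#' Compares two candidate tables at the variant level (canonical
#' `GENE:pos:REF/ALT` keys, see [make_variant_key()]) or at the peptide
#' level (augmented-peptide strings). Keys are case-normalized and
#' deduplicated within each set before counting, so the report is symmetric
#' and idempotent under duplication.
#'
#' @param set_a,set_b Candidate tibbles carrying a `variant_key` column
#'   (variant level) or an `augmented_peptide` column (peptide level);
#'   plain character vectors of keys are also accepted.
#' @param level `"variant"` or `"peptide"`.
#' @return An object of class `neo_overlap` with fields `n_a`, `n_b`,
#'   `n_overlap`, `jaccard`, `overlap_keys`; [tidy()] returns the matched
#'   keys, [glance()] the counts.
#' @export
overlap_candidates <- function(set_a, set_b,
                               level = c("variant", "peptide")) {
  level <- match.arg(level)
  a <- overlap_keys_of(set_a, level)
  b <- overlap_keys_of(set_b, level)
  ov <- intersect(a, b)
  denom <- length(a) + length(b) - length(ov)
  structure(
    list(n_a = length(a), n_b = length(b), n_overlap = length(ov),
         jaccard = if (denom > 0) length(ov) / denom else NA_real_,
         overlap_keys = sort(ov), level = level),
    class = "neo_overlap"
  )
}

overlap_keys_of <- function(x, level) {
  if (is.character(x)) return(unique(toupper(trimws(x))))
  col <- if (level == "variant") "variant_key" else "augmented_peptide"
  if (!col %in% names(x)) {
    abort(paste0("Candidate set lacks the '", col, "' column needed for ",
                 level, "-level comparison."))
  }
  unique(toupper(trimws(x[[col]])))
}

#' @export
print.neo_overlap <- function(x, ...) {
  cat(sprintf("Candidate-set overlap (%s level): |A| = %d, |B| = %d, shared = %d (Jaccard %.3f)\n",
              x$level, x$n_a, x$n_b, x$n_overlap,
              ifelse(is.na(x$jaccard), NaN, x$jaccard)))
  invisible(x)
}

#' @method tidy neo_overlap
#' @export
tidy.neo_overlap <- function(x, ...) {
  tibble(key = x$overlap_keys)
}

#' @method glance neo_overlap
#' @export
glance.neo_overlap <- function(x, ...) {
  tibble(n_a = x$n_a, n_b = x$n_b, n_overlap = x$n_overlap,
         jaccard = x$jaccard, level = x$level)
}

#' Cross-reference matching candidates between two top lists
#'
#' When the same variant appears in both an RNA-only and a conventional
#' top-N list, each record gains the matching record's id from the other
#' list (e.g. a conventional candidate labeled with the RNA list's `M6`).
#'
#' @param top_a,top_b Candidate tibbles with `neoantigen_id` and
#'   `variant_key` columns.
#' @return A list with elements `a` and `b`: the inputs with an added
#'   `cross_id` column (`NA` where no counterpart exists).
#' @export
annotate_overlap_ids <- function(top_a, top_b) {
  need <- c("neoantigen_id", "variant_key")
  stopifnot(all(need %in% names(top_a)), all(need %in% names(top_b)))
  key_a <- toupper(trimws(top_a$variant_key))
  key_b <- toupper(trimws(top_b$variant_key))
  list(
    a = mutate(top_a, cross_id = top_b$neoantigen_id[match(key_a, key_b)]),
    b = mutate(top_b, cross_id = top_a$neoantigen_id[match(key_b, key_a)])
  )
}

#' @method autoplot neo_overlap
#' @export
autoplot.neo_overlap <- function(object, ...) {
  df <- tibble(
    part = factor(c("A only", "shared", "B only"),
                  levels = c("A only", "shared", "B only")),
    n = c(object$n_a - object$n_overlap, object$n_overlap,
          object$n_b - object$n_overlap)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$part, y = .data$n)) +
    ggplot2::geom_col(fill = c("#4477AA", "#228833", "#CCBB44")) +
    ggplot2::labs(x = NULL, y = "candidates",
                  title = sprintf("Set overlap (%s level), Jaccard %.3f",
                                  object$level, object$jaccard)) +
    ggplot2::theme_minimal()
}
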