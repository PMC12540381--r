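FILTER_RULES <- c("TUMOR_DP", "NORMAL_DP", "TUMOR_AD", "NORMAL_AD",
                  "BASEQ", "SOR", "VAF", "TPM", "NO_EXPRESSION")

#' Filtering thresholds for RNA-seq somatic variants
#'
#' Bundles the cutoffs applied to RNA-seq-derived somatic variant calls.
#' Defaults: tumor depth >= 50x, normal depth >= 30x, tumor alt-allele depth
#' >= 5, normal (reference) allele depth >= 3, base quality >= Q20, strand
#' odds ratio <= 5.0, tumor VAF >= 5%, gene expression >= 1 TPM. All
#' comparisons are inclusive on the stated side.
#'
#' The normal-sample allele-depth rule is ambiguous as usually stated; by
#' default (`normal_ad_interpretation = "ref_support"`) it requires at least
#' `normal_ad_min` reference-supporting reads in the normal (the normal
#' genotype is evaluable). The alternative `"alt_at_most"` instead rejects
#' variants whose normal sample shows more than `normal_ad_min` alt-supporting
#' reads (germline contamination guard); with that interpretation callers
#' must supply a `normal_ad_alt` column.
#'
#' @param tumor_dp_min,normal_dp_min Minimum read depth (tumor / normal).
#' @param tumor_ad_min Minimum alt-supporting depth in the tumor.
#' @param normal_ad_min Normal-sample allele-depth cutoff (see Details).
#' @param base_quality_min Minimum site base quality (Phred).
#' @param sor_max Maximum strand odds ratio.
#' @param vaf_min Minimum tumor variant allele frequency, in `[0, 1]`.
#' @param tpm_min Minimum gene expression (TPM).
#' @param normal_ad_interpretation `"ref_support"` (default) or
#'   `"alt_at_most"`.
#' @return An object of class `neo_thresholds`.
#' @export
filter_thresholds <- function(tumor_dp_min = 50, normal_dp_min = 30,
                              tumor_ad_min = 5, normal_ad_min = 3,
                              base_quality_min = 20, sor_max = 5.0,
                              vaf_min = 0.05, tpm_min = 1.0,
                              normal_ad_interpretation = c("ref_support",
                                                           "alt_at_most")) {
  normal_ad_interpretation <- match.arg(normal_ad_interpretation)
  th <- list(
    tumor_dp_min = tumor_dp_min, normal_dp_min = normal_dp_min,
    tumor_ad_min = tumor_ad_min, normal_ad_min = normal_ad_min,
    base_quality_min = base_quality_min, sor_max = sor_max,
    vaf_min = vaf_min, tpm_min = tpm_min,
    normal_ad_interpretation = normal_ad_interpretation
  )
  num <- th[setdiff(names(th), "normal_ad_interpretation")]
  if (any(vapply(num, function(x) !is.numeric(x) || length(x) != 1 || is.na(x) || x < 0,
                 logical(1)))) {
    abort("All thresholds must be single non-negative numbers.")
  }
  if (th$vaf_min > 1) abort("vaf_min must lie in [0, 1].")
  structure(th, class = "neo_thresholds")
}

#' @export
print.neo_thresholds <- function(x, ...) {
  cat("RNA-seq variant filtering thresholds\n")
  cat(sprintf("  tumor DP >= %gx, normal DP >= %gx\n", x$tumor_dp_min, x$normal_dp_min))
  cat(sprintf("  tumor alt AD >= %g, normal AD rule: %s (%g)\n",
              x$tumor_ad_min, x$normal_ad_interpretation, x$normal_ad_min))
  cat(sprintf("  base quality >= Q%g, SOR <= %g, VAF >= %g, TPM >= %g\n",
              x$base_quality_min, x$sor_max, x$vaf_min, x$tpm_min))
  invisible(x)
}

#' Variant allele frequency from allele depth and total depth
#'
#' @param ad_alt Integer vector of alt-supporting read counts.
#' @param dp Integer vector of total read depths (> 0).
#' @return `ad_alt / dp`, elementwise.
#' @examples
#' compute_vaf(5, 50)   # 0.1
#' @export
compute_vaf <- function(ad_alt, dp) {
  if (any(dp == 0, na.rm = TRUE)) {
    abort("VAF undefined at zero depth (dp = 0).")
  }
  if (any(ad_alt < 0 | ad_alt > dp, na.rm = TRUE)) {
    abort("ad_alt must satisfy 0 <= ad_alt <= dp.")
  }
  ad_alt / dp
}

#' Apply the RNA-seq somatic-variant filtering cascade
#'
#' Evaluates every rule for every variant (no short-circuiting), so
#' `failed_rules` lists all violated cutoffs: tumor/normal depth, tumor
#' alt-allele depth, normal allele depth, base quality, strand odds ratio,
#' VAF, gene expression (TPM), and absence of the gene from the expression
#' table (`NO_EXPRESSION`). Rules whose underlying annotation is missing
#' (`NA` base quality or SOR) pass vacuously; when the run is tumor-only
#' (no normal sample columns, or attribute `tumor_only` on `variants`), the
#' normal-sample rules pass vacuously and the result carries a `tumor_only`
#' provenance attribute.
#'
#' @param variants Tibble of somatic variants (see [read_vcf()]).
#' @param expression Expression tibble (see [read_expression()]), joined at
#'   the gene level via `gene_symbol`.
#' @param gene_of Character vector (one gene symbol per variant, `NA` for
#'   intergenic), or a tibble with columns `variant_key` and `gene_symbol`.
#' @param thresholds A [filter_thresholds()] object.
#' @return A tibble of verdicts with columns `variant_key`, `gene_symbol`,
#'   `passed`, `failed_rules` (list column of rule names, in fixed rule
#'   order), `n_failed`.
#' @export
apply_filters <- function(variants, expression, gene_of,
                          thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "neo_thresholds"))
  v <- as_tibble(variants)
  key <- variant_site_key(v)
  if (is.data.frame(gene_of)) {
    gmap <- setNames(gene_of$gene_symbol, gene_of$variant_key)
    genes <- unname(gmap[key])
  } else {
    stopifnot(length(gene_of) == nrow(v))
    genes <- as.character(gene_of)
  }
  tpm_of <- setNames(expression$tpm, expression$gene_symbol)
  tpm <- unname(tpm_of[genes])

  tumor_only <- isTRUE(attr(variants, "tumor_only")) ||
    !("normal_dp" %in% names(v)) || all(is.na(v$normal_dp))

  fails <- list(
    TUMOR_DP = !vacuous(v$tumor_dp) & v$tumor_dp < thresholds$tumor_dp_min,
    NORMAL_DP = if (tumor_only) rep(FALSE, nrow(v))
                else !vacuous(v$normal_dp) & v$normal_dp < thresholds$normal_dp_min,
    TUMOR_AD = !vacuous(v$tumor_ad_alt) & v$tumor_ad_alt < thresholds$tumor_ad_min,
    NORMAL_AD = if (tumor_only) rep(FALSE, nrow(v))
                else normal_ad_fail(v, thresholds),
    BASEQ = !vacuous(v$base_quality) & v$base_quality < thresholds$base_quality_min,
    SOR = !vacuous(v$sor) & v$sor > thresholds$sor_max,
    VAF = !vacuous(v$vaf) & v$vaf < thresholds$vaf_min,
    TPM = !is.na(tpm) & tpm < thresholds$tpm_min,
    NO_EXPRESSION = is.na(tpm)
  )
  fail_mat <- do.call(cbind, fails)
  fail_mat[is.na(fail_mat)] <- FALSE

  out <- tibble(
    variant_key = key,
    gene_symbol = genes,
    passed = rowSums(fail_mat) == 0,
    failed_rules = purrr::map(seq_len(nrow(v)),
                              function(i) FILTER_RULES[fail_mat[i, ]]),
    n_failed = as.integer(rowSums(fail_mat))
  )
  attr(out, "tumor_only") <- tumor_only
  class(out) <- c("neo_verdicts", class(out))
  out
}

vacuous <- function(x) is.na(x)

normal_ad_fail <- function(v, th) {
  if (th$normal_ad_interpretation == "ref_support") {
    !vacuous(v$normal_ad_ref) & v$normal_ad_ref < th$normal_ad_min
  } else {
    if (!"normal_ad_alt" %in% names(v)) {
      abort("normal_ad_interpretation = 'alt_at_most' needs a normal_ad_alt column.")
    }
    !vacuous(v$normal_ad_alt) & v$normal_ad_alt > th$normal_ad_min
  }
}

variant_site_key <- function(v) {
  paste0(v$chrom, ":", v$pos, ":", toupper(v$ref_allele), ":",
         toupper(v$alt_allele))
}

#' Summarize a filtering run as a funnel
#'
#' Counts, per rule, how many variants violated it (one variant can count
#' against several rules) alongside the overall pass/fail totals.
#'
#' @param verdicts A verdict tibble from [apply_filters()].
#' @return An object of class `neo_filter_summary`; [tidy()] returns the
#'   per-rule failure counts, [glance()] a one-row overview.
#' @export
summarize_filtering <- function(verdicts) {
  rules <- unlist(verdicts$failed_rules)
  per_rule <- tibble(
    rule = FILTER_RULES,
    n_failed = unname(vapply(FILTER_RULES, function(r) sum(rules == r),
                             integer(1)))
  )
  structure(
    list(per_rule = per_rule,
         n_total = nrow(verdicts),
         n_pass = sum(verdicts$passed),
         tumor_only = isTRUE(attr(verdicts, "tumor_only"))),
    class = "neo_filter_summary"
  )
}

#' @export
print.neo_filter_summary <- function(x, ...) {
  cat(sprintf("Variant filtering: %d of %d variants pass%s\n",
              x$n_pass, x$n_total,
              if (x$tumor_only) " (tumor-only mode)" else ""))
  nz <- x$per_rule[x$per_rule$n_failed > 0, ]
  if (nrow(nz)) {
    for (i in seq_len(nrow(nz))) {
      cat(sprintf("  %-13s %d failed\n", nz$rule[i], nz$n_failed[i]))
    }
  }
  invisible(x)
}

#' @method tidy neo_filter_summary
#' @export
tidy.neo_filter_summary <- function(x, ...) x$per_rule

#' @method glance neo_filter_summary
#' @export
glance.neo_filter_summary <- function(x, ...) {
  tibble(n_total = x$n_total, n_pass = x$n_pass,
         n_fail = x$n_total - x$n_pass, tumor_only = x$tumor_only)
}
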