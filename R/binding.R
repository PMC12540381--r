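#' Peptide-MHC binding predictors
#'
#' Binding prediction is pluggable: any object of class `neo_predictor`
#' with a `predict_one(peptide, allele)` method can back epitope scoring.
#' Three predictors ship with the package:
#'
#' * [toy_predictor()] — a deterministic allele-seeded scorer for testing
#'   and examples (no external software, no randomness at call time);
#' * [table_predictor()] — replays a precomputed table of IC50s (e.g. an
#'   exported NetMHCpan/NetMHCIIpan run) and errors on unknown pairs;
#' * [external_predictor()] — wraps an external prediction command; it
#'   fails loudly when the binary is unavailable rather than silently
#'   degrading to the toy scorer.
#'
#' @name predictors
NULL

#' Deterministic built-in binding scorer
#'
#' Scores a peptide against an allele with an allele-seeded residue score
#' vector weighted along the peptide: anchor positions (position 2 and the
#' C-terminus, the class I anchor residues) carry double weight. The summed
#' score is mapped monotonically onto (0, 50000] nM, so higher scores give
#' lower IC50; repeated calls are bit-identical across runs and platforms.
#' This is a test stand-in with the same contract as a real predictor, not
#' a trained affinity model.
#'
#' @return A `neo_predictor` object.
#' @examples
#' p <- toy_predictor()
#' predict_binding("SIINFEKL", "H-2-Kb", predictor = p)
#' @export
toy_predictor <- function() {
  structure(
    list(id = "toy",
         predict_one = function(peptide, allele) toy_predict_one(peptide, allele)),
    class = "neo_predictor"
  )
}

# Platform-stable integer hash of a string (kept below 2^31).
string_seed <- function(s) {
  v <- utf8ToInt(s)
  h <- 0
  for (x in v) h <- (h * 131 + x) %% 2147483629
  as.integer(h)
}

allele_residue_scores <- function(allele) {
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(string_seed(paste0("mhc:", allele)))
  setNames(runif(20, 0, 1), AA_ALPHABET)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

toy_predict_one <- function(peptide, allele) {
  peptide <- toupper(peptide)
  k <- nchar(peptide)
  if (k < 8L || k > 15L) {
    abort(paste0("Toy predictor supports peptide lengths 8-15, got ", k, "."))
  }
  res <- strsplit(peptide, NULL)[[1]]
  if (!all(res %in% AA_ALPHABET)) {
    abort(paste0("Peptide contains non-amino-acid characters: ", peptide))
  }
  scores <- allele_residue_scores(allele)
  w <- rep(1, k)
  w[c(2L, k)] <- 2  # anchor positions
  s <- sum(w * scores[res]) / sum(w)        # in (0, 1)
  ic50 <- 50000 * plogis((0.5 - s) * 8)     # monotone decreasing in s
  tibble(peptide = peptide, allele = allele, ic50 = ic50,
         percent_rank = 100 * plogis((0.5 - s) * 6), source = "toy")
}

#' Precomputed-table binding adapter
#'
#' Replays binding results computed by an external engine. Lookups are
#' exact on (peptide, allele); a missing pair is an error, never a silent
#' fallback.
#'
#' @param table A tibble with columns `peptide`, `allele`, `ic50`, and
#'   optionally `percent_rank` (see [read_binding_table()]), or a file path
#'   to such a TSV.
#' @return A `neo_predictor` object.
#' @export
table_predictor <- function(table) {
  if (is.character(table)) table <- read_binding_table(table)
  stopifnot(all(c("peptide", "allele", "ic50") %in% names(table)))
  if (!"percent_rank" %in% names(table)) table$percent_rank <- NA_real_
  lut <- table
  keys <- paste0(toupper(lut$peptide), "|", lut$allele)
  structure(
    list(
      id = "table",
      predict_one = function(peptide, allele) {
        i <- match(paste0(toupper(peptide), "|", allele), keys)
        if (is.na(i)) {
          abort(paste0("No precomputed binding result for peptide ",
                       peptide, " / allele ", allele, "."))
        }
        tibble(peptide = toupper(peptide), allele = allele,
               ic50 = lut$ic50[i], percent_rank = lut$percent_rank[i],
               source = "table")
      }
    ),
    class = "neo_predictor"
  )
}

#' External prediction-engine adapter
#'
#' Thin wrapper around an external peptide-MHC prediction command. The
#' adapter checks for the binary at prediction time and raises an explicit
#' degraded-mode error when it is unavailable; it never falls back to the
#' built-in scorer silently.
#'
#' @param command Name of the external executable.
#' @param args_fun Function `(peptide_file, allele) -> character` building
#'   the argument vector.
#' @param parse_fun Function parsing the command's stdout into a tibble
#'   with columns `peptide`, `ic50`, `percent_rank`.
#' @return A `neo_predictor` object.
#' @export
external_predictor <- function(command = "netMHCpan", args_fun = NULL,
                               parse_fun = NULL) {
  structure(
    list(
      id = paste0("external:", command),
      predict_one = function(peptide, allele) {
        path <- Sys.which(command)
        if (!nzchar(path)) {
          abort(paste0(
            "External predictor '", command, "' is not available on this ",
            "system; refusing to degrade silently. Install it, or use ",
            "table_predictor() with a precomputed run."
          ))
        }
        if (is.null(args_fun) || is.null(parse_fun)) {
          abort("external_predictor() needs args_fun and parse_fun to run.")
        }
        pf <- tempfile(fileext = ".pep")
        writeLines(peptide, pf)
        out <- system2(command, args_fun(pf, allele), stdout = TRUE)
        res <- parse_fun(out)
        tibble(peptide = toupper(peptide), allele = allele,
               ic50 = res$ic50[1], percent_rank = res$percent_rank[1],
               source = paste0("external:", command))
      }
    ),
    class = "neo_predictor"
  )
}

#' Predict binding of peptides to an MHC allele
#'
#' Runs the given predictor for each peptide, preserving input order.
#' Results are memoized per (peptide, allele) within the predictor for the
#' duration of the session, so repeated queries are free and guaranteed
#' identical.
#'
#' @param peptides Character vector of peptides.
#' @param allele Allele name (as accepted by [parse_alleles()]); paired
#'   class II names are passed through combined.
#' @param predictor A `neo_predictor` (default [toy_predictor()]).
#' @return A tibble with columns `peptide`, `allele`, `ic50`,
#'   `percent_rank`, `source`, one row per input peptide.
#' @export
predict_binding <- function(peptides, allele, predictor = toy_predictor()) {
  if (!inherits(predictor, "neo_predictor")) {
    abort("`predictor` must be a neo_predictor (toy_predictor(), table_predictor(), ...).")
  }
  cache <- predictor_cache(predictor)
  purrr::map_dfr(peptides, function(p) {
    key <- paste0(toupper(p), "|", allele)
    hit <- cache[[key]]
    if (is.null(hit)) {
      hit <- predictor$predict_one(p, allele)
      cache[[key]] <- hit
    }
    hit
  })
}

predictor_cache <- function(predictor) {
  env <- attr(predictor, "cache")
  if (is.null(env)) {
    env <- new.env(parent = emptyenv())
    # predictors are list objects; attach the cache to the closure env so it
    # survives copies of the predictor value
    environment(predictor$predict_one)$.rnaneo_cache <- env
  }
  existing <- environment(predictor$predict_one)$.rnaneo_cache
  if (is.null(existing)) {
    existing <- new.env(parent = emptyenv())
    environment(predictor$predict_one)$.rnaneo_cache <- existing
  }
  existing
}

#' Apply the binder IC50 cutoff
#'
#' Retains results with IC50 strictly below the cutoff (default 500 nM, the
#' conventional candidate-epitope rule). A result exactly at the cutoff is
#' removed.
#'
#' @param results A tibble with an `ic50` column.
#' @param cutoff_nm Cutoff in nM.
#' @return The filtered tibble.
#' @export
candidate_cutoff <- function(results, cutoff_nm = 500) {
  stopifnot("ic50" %in% names(results))
  filter(results, .data$ic50 < cutoff_nm)
}

#' Score enumerated epitopes against typed alleles
#'
#' Predicts mutant (and, where present, wild-type) binding for every
#' epitope against every allele with the same predictor, the natural input
#' to per-variant best-epitope selection.
#'
#' @param epitopes Tibble from [enumerate_epitopes()].
#' @param alleles Character vector of allele names, or a parsed allele
#'   tibble (see [parse_alleles()]).
#' @param predictor A `neo_predictor`.
#' @return `epitopes` crossed with alleles, with added columns `allele`,
#'   `mut_ic50`, `wt_ic50`, `mut_rank`.
#' @export
score_epitopes <- function(epitopes, alleles, predictor = toy_predictor()) {
  if (is.data.frame(alleles)) alleles <- alleles$raw_name
  purrr::map_dfr(alleles, function(al) {
    mut <- predict_binding(epitopes$mut_peptide, al, predictor)
    has_wt <- !is.na(epitopes$wt_peptide)
    wt_ic50 <- rep(NA_real_, nrow(epitopes))
    if (any(has_wt)) {
      wt <- predict_binding(epitopes$wt_peptide[has_wt], al, predictor)
      wt_ic50[has_wt] <- wt$ic50
    }
    bind_cols(epitopes,
              tibble(allele = al, mut_ic50 = mut$ic50,
                     wt_ic50 = wt_ic50, mut_rank = mut$percent_rank))
  })
}
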