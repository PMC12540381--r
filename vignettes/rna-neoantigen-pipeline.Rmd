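---
title: "Identifying neoantigens from tumor RNA sequencing alone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying neoantigens from tumor RNA sequencing alone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaneo)
library(dplyr)
```

## The problem

Personalized neoantigen vaccines require three data layers: somatic
variants, the patient's (or animal's) MHC genotype, and tumor gene
expression. The standard route obtains the first from tumor/normal exome
sequencing and the rest from RNA-seq, which is costly and slow. Because
RNA-seq by itself carries variant, expression and HLA information, a tumor
transcriptome alone can in principle drive the whole pipeline — at the cost
of calling variants from RNA, which demands stringent quality filtering.
`rnaneo` implements that RNA-only pipeline as composable, testable pieces:

1. **Variant filtering** — depth, allele depth, base quality, strand bias,
   VAF and expression cutoffs applied to RNA-derived somatic calls.
2. **Consequence annotation** — codon-accurate mapping of passing variants
   onto transcript models.
3. **Epitope enumeration** — all mutant 8–11-mers containing the altered
   residue, each paired with its wild-type counterpart.
4. **Binding prediction** — a pluggable predictor interface (external
   engines are adapted, never reimplemented).
5. **Priority scoring and selection** — a weighted multi-dimensional score
   and deterministic top-N ranking.
6. **Long-peptide design** — 27- or 31-mer synthesis templates centered on
   the mutation.
7. **Set comparison** — overlap reports between RNA-only and conventional
   candidate lists.

## Filtering model

A variant is kept only if every rule holds; all rules are evaluated for
every variant (no short-circuiting) so that funnel reports carry complete
failure reasons. Defaults, inclusive on the stated side:

| rule        | cutoff                    | unit  |
|-------------|---------------------------|-------|
| TUMOR_DP    | depth ≥ 50                | reads |
| NORMAL_DP   | depth ≥ 30                | reads |
| TUMOR_AD    | alt-supporting depth ≥ 5  | reads |
| NORMAL_AD   | see below, default ≥ 3    | reads |
| BASEQ       | site base quality ≥ 20    | Phred |
| SOR         | strand odds ratio ≤ 5.0   | —     |
| VAF         | alt fraction ≥ 0.05       | —     |
| TPM         | gene expression ≥ 1       | TPM   |

Three points needed a design decision:

* **The normal-sample AD rule.** "Allele depth ≥ 3 in the normal" cannot
  sensibly require *alt*-supporting reads in a somatic filter — that would
  demand germline contamination. The default interpretation requires at
  least 3 *reference*-supporting reads (the normal genotype is evaluable);
  a configuration switch (`normal_ad_interpretation = "alt_at_most"`)
  instead rejects variants with more than 3 alt reads in the normal.
* **Base quality.** RNA-seq variant callers disagree on where a site-level
  base-quality summary lives. The reader takes INFO `MBQ` when present and
  falls back to the record `QUAL`, recording which was used in
  `baseq_source`; missing annotations are `NA`, never silently zero, and a
  rule whose input is `NA` passes vacuously rather than failing variants
  for absent metadata.
* **Tumor-only mode.** Cell lines have no matched normal; when no normal
  sample is given the two NORMAL_* rules pass vacuously and the verdict
  table carries a `tumor_only` provenance attribute.

Expression is joined at the *gene* level by symbol (candidate tables in
this field report gene symbols, and expression is quantified per gene);
variants on genes absent from the expression table fail `NO_EXPRESSION`.

## Consequence annotation and epitope enumeration

Transcript models are built from GFF3 CDS features plus a genome FASTA;
the spliced CDS is translated with the standard nuclear code
(reverse-strand models via reverse complement) and validated against the
stored protein. A variant is re-applied to the genomic sequence of the CDS
interval containing it, the mutant CDS is re-spliced and re-translated,
and the consequence is classified as missense, synonymous, stop-gain,
in-frame indel, or frameshift (translated through the first novel stop).
When several transcripts of one gene overlap a variant, the longest
transcript is kept, so downstream keys (`GENE:pos:REF/ALT`) are
gene-level.

For a missense at residue $p$ of an $L$-residue protein, the enumeration
emits every $k$-mer window covering $p$ for $k \in \{8,9,10,11\}$ — at an
interior site exactly $8+9+10+11 = 38$ mutant/wild-type pairs, fewer near
the termini (clipped windows, verified against brute-force enumeration in
the tests). Frameshift peptides tile the entire novel C-terminal sequence
and carry no wild-type partner; in published screens indel-derived
peptides are typically curated manually, so this enumeration is an
explicit interpretation, flagged as such. Class II prediction
conventionally uses ~15-mers; the predictor interface accepts lengths up
to 15, and the enumeration length set is a parameter.

## Binding predictors

External engines (NetMHCpan-class tools) are adapted, never reimplemented:

* `table_predictor()` replays a precomputed TSV of (peptide, allele, IC50,
  %rank) exactly and errors on unknown pairs.
* `external_predictor()` shells out to an installed binary and raises an
  explicit error when the binary is absent — no silent fallback.
* `toy_predictor()` is a deterministic stand-in for tests and examples: an
  allele-seeded residue score vector, doubled in weight at the class I
  anchor positions (position 2 and the C-terminus), mapped monotonically
  onto (0, 50000] nM through a logistic. It has the same contract as a
  real predictor (determinism, bounded IC50, allele specificity) and *no*
  biological validity; its rank-one construction makes anchor sensitivity
  and score–IC50 monotonicity provable properties rather than empirical
  ones.

Mutant and wild-type members of a pair are always scored by the same
predictor, so the differential is internally consistent.

## Priority score

Published screens of this kind describe their ranking as a weighted
combination of binding differential, expression, VAF, DNA–RNA concordance
and presentation likelihood, but do not publish the weight vector or the
sub-score transforms. The score here is therefore an explicit
reconstruction; printed priority scores from any specific published table
are **not** a validation target. Each dimension maps to $[0,1]$:

* $s_\text{binding} = \mathrm{clamp}\!\left(1 -
  \frac{\log \mathrm{IC50}_\text{mut}}{\log 50000},\,0,\,1\right)$,
  optionally multiplied by a wild-type differential factor
  $\left(\mathrm{clamp}(\log_{10}(\mathrm{IC50}_\text{wt}/
  \mathrm{IC50}_\text{mut}), 0, 1) + b\right)/(1+b)$ with baseline
  $b = 0.5$, so a mutant-specific binder scores up to 3× a
  mutant-equals-wild-type binder while the product stays in $[0,1]$.
* $s_\text{expr} = \log(1+\mathrm{TPM}) / (\log(1+\mathrm{TPM}) +
  \log(1+h))$, a saturating map with half-saturation at $h = 10$ TPM —
  around the median expression of protein-coding genes, so the score
  discriminates in the biologically relevant range instead of being
  dominated by a few highly expressed genes.
* $s_\text{VAF}$ is the VAF itself.
* $s_\text{conc}$ is 1 when a matched DNA call supports the variant. In an
  RNA-only run there is no DNA, so it is 1 by definition — a provenance
  note, not evidence — and its weight can be zeroed.
* $s_\text{pres} = 1 - \text{\%rank}/100$ when the predictor reports a
  percentile rank, else 0.5 (uninformative).

The priority score is $100 \sum_i w_i s_i$ with weights normalized to sum
to one (equal by default, all configurable), hence always in $[0, 100]$.
Ranking is deterministic: descending score, ties broken by lower mutant
IC50, higher TPM, gene symbol, then variant key.

**Cutoff policy.** The conventional-route convention applies a strict
IC50 < 500 nM gate before ranking. RNA-only screens in practice rank
candidates whose best IC50 is far above 500 nM (weak binders can still be
vaccine-relevant through class II presentation of the long peptide), so in
`mode = "rna"` no hard IC50 gate is applied and the binding sub-score
carries the information instead. `run_pipeline(mode = "conventional")`
applies the strict gate. This split reconciles an inconsistency in how the
two routes are described in the literature, and makes it explicit.

## Long-peptide design

Synthesis templates are 27- or 31-mers (27 for the LLC screen, 31 for the
4T1 and patient screens; no published rationale for the difference, so the
window is a per-run parameter defaulting to 31). The centering rule is
inferred from the published full-length peptides: the mutant residue sits
at index 16 of a 31-mer and index 14 of a 27-mer. Near a protein terminus
the window *slides* to keep its full length rather than shrinking — the
published tables contain exactly such rows (a 31-mer starting at the
protein's N-terminal methionine with the mutation at index 7, and three
patient rows with off-center mutations), which is how the slide rule was
identified. Only when the protein itself is shorter than the window is the
whole protein returned, flagged `truncated`.

## The synthetic cohort generator

Real deposited reads, a commercial variant caller, and a licensed binding
predictor are all outside this package's scope, so every stage is
exercised against generated cohorts with known ground truth
(`generate_cohort()`):

* a genome of single-gene contigs (proteins of 80–250 residues; optional
  multi-exon and reverse-strand models to exercise splicing and strand
  code);
* somatic variants planted at chosen consequence classes (80% missense by
  default, the remainder synonymous and 1-bp frameshift deletions), with
  tumor depth ~ NegBin(mean 120, size 8), normal depth ~ NegBin(mean 60),
  VAF ~ Beta(2, 2) — cell-line-like, most VAFs high — and log-normal TPM
  (meanlog 1, sdlog 1.5); 5% of genes are withheld from the expression
  table to exercise the `NO_EXPRESSION` rule;
* a truth table recording, for every variant, its realized metrics, its
  protein consequence derived by an independent generation-time
  translation (a plain codon-table walk, deliberately not the annotation
  code path), and the expected outcome of every filter rule.

Bundles are a pure function of the configuration (including the seed):
generating twice gives byte-identical files. Default test problem sizes —
tens of genes, 20–150 variants, 500–1000 draws for distributional checks —
were chosen so each property has statistical teeth while the whole suite
runs in a few minutes.

What the generator does *not* emulate: read-level errors, alignment
artifacts, splicing mis-annotation, RNA editing, allele-specific
expression, or any real linkage between expression and mutation rate.
Passing the end-to-end tests therefore demonstrates that the pipeline's
logic is faithful to its stated rules, not that the rules themselves are
optimal for real tumors.

## Worked example

```{r example}
cfg <- cohort_config(n_genes = 30, n_variants = 60, seed = 202)
bundle <- generate_cohort(cfg, file.path(tempdir(), "demo"))

variants <- read_vcf(bundle$paths$vcf, "TUMOR", "NORMAL")
models <- read_transcript_models(bundle$paths$gff3, bundle$paths$genome)
expression <- read_expression(bundle$paths$expression)

run <- run_pipeline(variants, models, expression,
                    alleles = c("H-2-Kd", "H-2-Dd"), top_n = 10)
run

run$candidates %>%
  select(neoantigen_id, hla_allele, amino_acid_change, gene_symbol,
         mut_mhc_ic50, priority_score) %>%
  head(5)
```

The filtering funnel and candidate landscape have plot helpers:

```{r plots, fig.width = 6, fig.height = 3.5}
plot_filter_funnel(run$summary)
plot_priority(run$candidates)
```

Comparing an RNA-only and a conventional candidate list:

```{r compare}
rna <- reported_candidates("4t1_rna")
conv <- reported_candidates("4t1_conventional")
ov <- overlap_candidates(rna, conv, level = "variant")
ov
annotate_overlap_ids(conv, rna)$a %>%
  filter(!is.na(cross_id)) %>%
  select(neoantigen_id, cross_id, gene_symbol, amino_acid_change)
```

## Known limitations

* RNA-only calling cannot distinguish somatic variants from RNA editing or
  unfiltered germline variation beyond the stated thresholds; no
  panel-of-normals logic is included.
* Splice-junction, fusion and non-coding neoantigens are out of scope, as
  is proteasomal-processing prediction.
* The toy predictor is a contract stand-in; any scientific use requires a
  real engine behind `table_predictor()` or `external_predictor()`.
* Priority-score weights are unvalidated defaults; ranking changes with
  the weight vector, and the package deliberately exposes this rather than
  hiding it.
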