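---
title: "Methods: cross-species DEG comparison and YAP/TAZ–TEAD target prediction"
author: "regumirror"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species DEG comparison and YAP/TAZ-TEAD target prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regumirror)
```

## The scientific problem

Vascular smooth muscle cells (VSMCs) lose their contractile identity during
atherosclerosis, and the transcriptional co-activators YAP/TAZ, acting
through TEAD transcription factors, are central regulators of that switch.
Two analytical questions recur in this setting:

1. **How similar are transcriptional responses across datasets and
   species?** Given differential-expression (DEG) tables from, say, a
   VSMC-specific YAP/TAZ knockout and from atherosclerotic lesions, one
   wants overlap statistics, direction concordance, fold-change
   correlations, and functional enrichment of the shared signature.
2. **Which dysregulated genes are *direct* YAP/TAZ–TEAD targets?** Loss of
   a master regulator perturbs thousands of genes indirectly. Direct
   targets are nominated by a funnel that demands convergent evidence:
   promoter-proximal ChIP-seq binding of YAP1 and at least one TEAD factor
   in both human and mouse, a TEAD binding motif in the bound peaks, and
   consistent downregulation after knockout.

`regumirror` implements both as a tested, seedable pipeline over standard
file formats, with a synthetic-data module that generates every input with
known ground truth, so the whole analysis is verifiable offline.

## Comparison statistics

**DEG definition.** A gene is a DEG when its BH-adjusted p-value satisfies
`padj < alpha` (strict), with `alpha = 0.05` by default. Records with a
missing `padj` are treated as non-significant: this is the conservative
choice, and it means a gene can never enter a comparison on the strength of
a missing value.

**Overlap testing.** For two DEG sets of sizes $K$ and $n$ drawn from a
background of $N$ analyzed genes, the overlap $k$ is tested with the
one-sided hypergeometric upper tail

$$P = \sum_{x \ge k} \frac{\binom{K}{x}\binom{N-K}{n-x}}{\binom{N}{n}},$$

inclusive of the observed $k$ — the standard enrichment convention. The
expected overlap $nK/N$ is reported alongside. The background $N$ is the
union of all analyzed (tested, not merely significant) genes; because this
union depends on the upstream platforms, **the caller must supply it
explicitly** — the package deliberately has no silent default, and
`compare_deg_tables()` errors without one.

**Concordance and correlation.** Direction concordance is the fraction of
shared significant DEGs whose log2 fold changes agree in sign; genes with a
fold change of exactly zero are excluded from numerator and denominator
(the generator never produces them, and real DE tables essentially never
contain exact zeros). Fold-change similarity uses Spearman's rho computed
as the Pearson correlation of average ranks (mid-ranks for ties) with the
large-sample t approximation for the p-value; at the sample sizes where
these comparisons are meaningful (tens to thousands of shared genes) the
exact permutation null is unnecessary.

**Multiple testing.** All adjusted p-values use the Benjamini–Hochberg
step-up procedure (`stats::p.adjust`). One property worth stating
precisely: BH output re-sorted by raw p is monotone, and the
monotone-repair step (cumulative minimum from the largest rank) is
idempotent, but the full BH operator applied to its own output is *not*
the identity — re-application rescales by $m/\text{rank}$ again. The test
suite asserts the two true properties.

**Enrichment.** Over-representation analysis reuses the same
hypergeometric machinery over any GMT catalog, after intersecting each
term with the background and keeping terms with 10–500 background members
(configurable; the defaults follow common enrichment practice). Redundant
significant terms are collapsed by single-linkage clustering at Jaccard
similarity ≥ 0.7 of member sets, keeping the minimum-padj representative
per cluster. We use set-membership (Jaccard) similarity rather than
ontology-graph semantic similarity: it requires nothing beyond the catalog
itself, behaves identically for non-ontology catalogs (pathway
collections, marker sets), and at the 0.7 cutoff removes the same
identical-or-nested duplicates that motivate simplification in the first
place.

## Ranked GSEA

The enrichment score is the classical weighted Kolmogorov–Smirnov running
sum: walking the ranked list, in-set genes add
$|r_i|^w / \sum_{j \in S}|r_j|^w$ and out-of-set genes subtract
$1/(N-|S|)$; the ES is the extremum of largest magnitude (positive on
ties), and the leading edge collects the members at or before a positive
extremum (at or after, for a negative one). `weight = 1` is the default,
`weight = 0` gives the unweighted statistic.

Significance uses a **gene-permutation null**: the set's in-list members
are re-drawn uniformly at random `n_perm` times (default 10,000, seed
mandatory), and

$$p = \frac{1 + \#\{b : \operatorname{sign}(ES_b) = \operatorname{sign}(ES),\ |ES_b| \ge |ES|\}}{1 + \#\{b : \operatorname{sign}(ES_b) = \operatorname{sign}(ES)\}},$$

with NES = ES divided by the mean |null ES| of the same sign — the
canonical sign-stratified convention. The add-one pseudocount makes the
smallest attainable p-value $1/(1 + n_{\text{same}})$, where
$n_{\text{same}}$ (reported in the output) is the same-sign null count,
roughly half of `n_perm` for a sign-balanced ranking. We chose plain gene
permutation over adaptive multilevel refinement because it is exactly
testable: the null is explicit, deterministic under the seed, and its
calibration can be verified by simulation (the suite checks that random
sets reject at 3–7% for a nominal 5% level). The price is a p-value floor;
analyses needing p-values far below $1/n_{\text{perm}}$ should raise
`n_perm` rather than extrapolate.

Null scores are computed by a vectorized routine that evaluates the
running-sum extremum directly from sorted hit positions; a test asserts it
agrees exactly with the step-by-step running sum.

## The target-prediction funnel

Inputs per species: per-factor narrowPeak files (YAP1, TEAD1–4; several
files per factor are concatenated, mirroring pooled ChIP evidence across
cell types), a blacklist BED, a TSS annotation (GTF or BED6), and the
genome FASTA; plus TEAD PFMs (JASPAR text), a human–mouse ortholog table,
and the two knockout DEG tables. All coordinates are normalized to 0-based
half-open on ingestion.

The stages, each deterministic:

1. **Blacklist removal** — any peak intersecting a blacklist interval by
   ≥ 1 bp is dropped (half-open semantics: abutting intervals do not
   touch).
2. **Promoter assignment** — promoter windows are `[tss − 2000, tss +
   2000)`, strand-independent (only the TSS position itself is
   strand-aware; with a symmetric window, strand flipping would change
   nothing), clipped at the chromosome start. A peak is promoter-bound for
   a gene if it overlaps any of that gene's windows; per gene and factor
   the highest-scoring peak is kept, ties broken by smaller start then
   chromosome name so outputs are reproducible.
3. **Score repair and tiers** — the narrowPeak score is defined as
   `round(−log10(q) × 10)`; some peak emitters zero the score column, so a
   zero score with a q-value present is repaired from that definition (and
   logged). Scores map onto the five-tier intensity scale: blue < 200,
   cyan 200–499, green 500–749, yellow 750–999, red ≥ 1000.
4. **Occupancy filter** — a gene passes a species when it has a YAP1 best
   peak and at least one TEAD1–4 best peak.
5. **Cross-species consensus** — ortholog pairs passing in both species.
   A human gene with several mouse orthologs qualifies if *any* pairing
   passes; one row per human gene is emitted (first qualifying mouse
   symbol alphabetically) with the multiplicity logged.
6. **Motif filter** — TEAD PWM matches are sought in the promoter-bound
   peak intervals of either species (not the full ±2 kb window; peaks are
   where the binding evidence is — scanning the whole window is available
   via `scan_windows = TRUE`). Matching uses log2-odds scores against a
   uniform background (configurable) with pseudocount 1, at a match
   p-value of `5e-5`, the common default for PWM scanners.
7. **Knockout intersection** — surviving genes must satisfy `padj < 0.05`
   and `log2fc < 0` in **both** the 2-week and 8-week knockout tables.

`run_funnel()` returns the panel, per-stage survivor counts (the analog of
a published funnel's attrition series), and a per-gene record of the first
stage at which each input gene left the funnel.

**PWM thresholds** are computed exactly, not by sampling: per-column score
distributions under the background are convolved on a discretized grid
(bin width 0.001 bits, well under the 0.01-bit cap), giving the full score
distribution; the threshold is the smallest attainable score whose upper
tail is ≤ the match p-value. Two consequences are worth knowing. First,
for very short or very sharp motifs no attainable score may satisfy a
stringent p-value (the consensus itself carries more than `p_cutoff`
probability); the threshold is then `Inf` and nothing can match — a real
property of short motifs, not an implementation artifact. Second, a
sequence whose exact score lies within `width × bin` of the cutoff
boundary can land on either side of the discretized threshold; the tests
therefore compare thresholds to exhaustive enumeration with exactly that
band, and verify the realized background hit rate directly. Windows
containing `N` never match. Minus-strand hits are reported at the
forward-strand offset of the matched window.

## The synthetic-data module

`gen_deg_pair()` builds two DEG tables over a shared universe with an
exact number of shared significant genes (`round(overlap_target ×
n_deg_b)`), sign agreement with probability `concordance_target` (a
binomial draw: with 2000 shared genes the estimate carries a standard
error of about 0.007), and fold-change magnitudes `|N(0, lfc_sd)| + 0.25`
— the offset guarantees no zero-sign ambiguity, and shared-gene magnitudes
are positively coupled so that rank correlation rises with concordance.
Significant genes draw `padj` uniformly below 0.05, the rest above.

`gen_gene_sets()` plants enrichment by sampling designated sets with
elevated odds from a query list; unplanted sets are uniform draws.

`gen_regulatory_fixture()` writes a complete two-species regulatory
dataset: pseudo-genomes (one 6 kb block per gene, so promoters sit ≥ 2 kb
apart and windows never collide), TSS BED6 files alternating strands,
per-factor narrowPeak files with scores sampled across all five tiers
(about a fifth with a zeroed score column to exercise the repair path), a
blacklist covering the designated decoys' peaks, an ortholog table, the
TEAD PFM (width 10: a strong GGAATG core with weakly informative flanks —
the flanks keep the exact score distribution wide enough that a `5e-5`
threshold is attainable, which a bare width-6 core cannot satisfy), and
the two knockout DEG tables. Planted targets pass every gate: the full PWM
consensus (which scores the attainable maximum) is written into one
promoter peak per species. Each decoy violates exactly one gate —
blacklisted peaks, no YAP1 peak, no TEAD peak, missing ortholog entry, no
motif (the peak interval is rejection-sampled free of threshold-level
matches, then a one-mismatch near-miss of the consensus is planted to
stress the threshold), or flipped regulation at exactly one time point.
Everything is a pure function of the seed; two runs with equal seeds are
byte-identical.

What the generator does **not** emulate: read-level noise, fragment-size
and GC biases in ChIP signal, correlated gene programs, overlapping or
bidirectional promoters, and many-to-many ortholog tangles beyond simple
one-to-many cases. Passing tests on the fixture therefore demonstrate that
the statistical and set logic is correct under the stated constructions,
not that the pipeline is robust to every pathology of real data.

## Orchestration and reproducibility

`run_pipeline()` drives compare → enrich → gsea → funnel → panel from a
YAML config (or equivalent list). Every stochastic stage requires an
explicit seed in the config — there is no wall-clock fallback. Outputs are
TSV/JSON with stable formatting and timestamp-free logs, so two runs with
the same config and seeds are byte-identical; a failed stage aborts
downstream stages but preserves completed outputs, and `summarize_run()`
aggregates whatever is present, marking missing stages. A thin
command-line wrapper ships in `inst/scripts/regumirror.R`; the exported
functions are the primary interface.

## Problem sizes and numerical choices

The test suite verifies the hypergeometric/ORA/Fisher p-values against an
exact big-integer enumeration oracle (backgrounds up to 60 genes, over a
thousand random configurations), BH against a literal step-up oracle, the
GSEA running sum against a step-by-step reimplementation, and PWM
thresholds against exhaustive 4^w enumeration up to width 8. End-to-end
checks use fixtures of 19 planted targets with 3 decoys per stage across
10 seeds, DEG pairs of 6000 genes with 2000 shared DEGs, GSEA calibration
with 500 replicate null sets at 2000 permutations, and a 10^6-position
background scan for the motif hit rate. These sizes were chosen so the
oracles stay exact and the planted effects dwarf sampling noise while the
whole suite runs in minutes on one CPU.

Tie-breaks are deterministic everywhere (score, then position, then
lexicographic labels; padj then symbol for gene rankings). Degenerate
inputs have defined behavior: empty DEG tables filter to empty tables,
`k = 0` overlaps give p = 1, a gene set covering the whole ranked list is
an error rather than a zero-division, and an all-`N` sequence yields no
motif hits.

## Known limitations

* The funnel nominates *putative* direct targets; with real data, its
  output quality is bounded by the provenance of the peak files, the TSS
  annotation release, and the ortholog table — all consumed as given.
* The hypergeometric background must be supplied by the caller; results
  are sensitive to it, which is why it is a required argument.
* The GSEA p-value floor is set by the same-sign permutation count;
  deeply significant sets need larger `n_perm`.
* Redundancy simplification by Jaccard similarity will not merge terms
  that are semantically close but share few members (e.g. sibling GO
  terms with disjoint annotation sets).
* Motif scanning assumes an i.i.d. background; promoter composition bias
  (CpG islands) is not modeled.
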