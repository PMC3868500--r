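---
title: "Methods: two-library small RNA analysis with smallrnadx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-library small RNA analysis with smallrnadx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smallrnadx)
```

## The design this package addresses

Early small-RNA profiling studies of membranous nephropathy (MN)
pooled all case specimens into one sequencing library and all normal
controls (NC) into another, so the unit of comparison is a *pair of
libraries*, not a set of replicated samples. Every statistic in this
package is built for that two-column world: counts `x` (NC) and `y`
(MN) with library clean totals `N1` and `N2`. This is deliberately not
a replicate-aware model (no negative-binomial dispersion estimation as
in DESeq2/edgeR); with one library per group there is nothing to
estimate dispersion from, and the Audic–Claverie statistic is the
classical answer for that regime.

## Cleaning model

Raw reads are fixed-length tags (default 50 nt) consisting of a small
RNA insert followed by the 3' adaptor. Cleaning applies, in order:

1. **Quality filter** — retain reads with mean Phred ≥ 20 and N-base
   fraction ≤ 10%. The source protocol only states that low-quality
   reads were removed "in accordance with the base quality value";
   these two thresholds are conventional small-RNA QC defaults and are
   explicit, configurable parameters so the rule is reproducible.
2. **3' adaptor trimming** — the leftmost exact match of the
   adaptor's first 8 nt marks the insert end. Matching is exact (no
   mismatches) by design: at desk scale determinism and a clean oracle
   are worth more than the recall a fuzzy matcher would add. Inserts
   must fall in 18–30 nt (the typical mature-miRNA range, configurable);
   everything else is discarded with a tallied reason
   (`no_adaptor` / `too_short` / `too_long`).
3. **5' contaminant removal** — tags whose prefix equals the 5'
   adaptor seed are ligation artifacts and dropped.
4. **Collapsing** — exact-sequence de-duplication into a
   `tag_library` of unique tags with read counts; the clean total `N`
   of the library is the per-million denominator downstream.

Every read is accounted for: input = clean + Σ removed-by-reason, and
the pipeline manifest re-checks this conservation on each run.
Sequences are held in the DNA alphabet internally (U→T) and rendered
as RNA in miRNA-facing reports.

## Mapping

The mapper is an exact substring search over both strands (a tag maps
antisense where its reverse complement occurs). Overlapping
occurrences are all reported. Two mapped fractions are kept separate,
as in the published mapping tables: the *unique* fraction (distinct
tag sequences with ≥ 1 hit) and the *total* fraction (read-weighted).
A multi-mapping tag counts once for "mapped?" but contributes its
reads at every locus in the per-chromosome sense/antisense tallies,
because the chromosome plot shows locus occupancy while the summary
shows mapped fractions. Percentages are exact (`100·mapped/total`)
until report formatting, which rounds half-up to one decimal — the
published table's two-decimal figures are internally inconsistent with
its own counts at the second decimal, so one decimal is the precision
the numbers actually support.

## Counting and base composition

A tag is assigned to a mature miRNA only on exact full-length identity
(no isomiR shifts). This keeps the unannotated pool well defined for
the edit stage: anything not exactly known is a candidate edit.
Duplicate mature sequences are an error rather than a silent merge.
Base composition is computed count-weighted over miRNA-assigned tags
for positions 1–24 by default; a tag shorter than position *p* simply
does not contribute at *p*, and each covered position row sums to 100.
Whether the published composition table was computed over all tags or
only miRNA-aligned ones is not stated in its source; this package
computes it over miRNA-aligned tags (the table sits under a "known
miRNA alignments" heading) but `base_composition()` accepts any tag
set, so the all-tags variant is one call away.

## Differential expression

* **Normalization**: `c/N × 10⁶`, floored at 0.01. The floor is the
  convention visible in the published top tables, where miRNAs absent
  from one library print as 0.01; it also guarantees the fold change
  `log₂(MN/NC)` is always defined.
* **Audic–Claverie point probability**: the printed formula
  `P(y|x) = (N₂/N₁)^y (x+y)! / (x! y! (1+N₂/N₁)^{x+y+1})`, evaluated
  with log-gamma in log space so counts up to 10⁷ neither overflow nor
  underflow. An independent exact evaluator (`ac_point_exact()`,
  arbitrary-precision integer arithmetic on base-10⁷ limbs) exists for
  small instances and anchors the test suite; conditional on `x` the
  formula is also a negative-binomial pmf, which gives a second,
  closed-form cross-check.
* **Tail mode**: `ac_pvalue(mode = "tail")` is the minimal-likelihood
  exact p-value — the sum of every outcome no more probable than the
  observed one, capped at 1. The pmf over `y'` is unimodal, so the sum
  is two negative-binomial tails; the cut points are found by
  bisection and the tails evaluated through the regularized incomplete
  beta function. A direction-selected one-sided tail was considered
  and rejected: choosing the tail after seeing the data doubles the
  null rejection rate (~2α), while the minimal-likelihood sum is
  conservative, which the type-I simulation in the acceptance tests
  verifies.
* **Default mode is `point`**: the published analysis prints only the
  point formula, and its table p-values match neither the point nor
  any tail convention exactly, so the printed formula is the
  defensible default; `tail` is available and is what the type-I
  guarantee is stated for.
* **Calls**: up/down require `P ≤ 0.01` *and* `|log₂ FC| ≥ 1`. The
  fold-change threshold 1.0 is inferred from the smallest reported
  significant effect (|FC| = 1.03) in the source tables; setting it to
  0 recovers a pure `P ≤ 0.01` rule. No multiple-testing correction is
  applied to calls (none was applied in the source analysis); a
  Benjamini–Hochberg column is emitted as supplementary output only.

## Seed edits

Mature-miRNA positions 2–8 are the seed region. Candidate edits are
unannotated tags that match a mature sequence of the *same length*
with exactly one mismatch inside the seed — no indels or shifted
alignments, since the phenomenon of interest is substitution. A tag
equal to some mature sequence is exact for that miRNA and never an
edit of another (exactness trumps edit); a tag one mismatch from
several matures is tallied for each and flagged. Per miRNA and group,
the edit percentage is `100·edited/(edited+exact)` over read counts
(distinct-tag denominators are a switch, since the published table
does not say which it used). The MN/NC ratio is rounded half-up to two
decimals *before* classification into >1 / =1 / <1 — that reproduces
the published "=1" block, which contains pairs like 100.00/99.55.
Ratios with a zero NC percentage are reported as undefined and
excluded from the three-class partition, whose counts always sum to
the classified total.

## qPCR

`ΔCt = Ct_target − Ct_reference` per group, `ΔΔCt = ΔCt_MN − ΔCt_NC`,
ratio `2^−ΔΔCt`, log2 ratio `−ΔΔCt`. The source description of the
sign convention is garbled in print; the worked arithmetic of its own
validation table (which these formulas reproduce at two decimals for
all five assayed miRNAs) is taken as definitive. Replicate Ct rows are
averaged (optionally median) before ΔCt, and the reference gene is
simply whatever was measured as the reference column (U6 in the
bundled table).

## Pair matrix and clustering

For multi-pair designs each pair contributes a fold-change vector; a
cell is missing exactly when the miRNA was floored (absent) in either
member of the pair, so absence is never treated as an extreme effect.
Distances between rows/columns are computed pairwise-complete over
observed cells (Euclidean rescaled as `stats::dist` does, or
1 − Pearson), and missing values never enter a distance; a pair of
rows or columns with no shared observation is an error naming the
offenders rather than a silent NaN. Defaults are Euclidean distance
with average linkage — the source figure names no method, so both are
documented, configurable choices.

## Synthetic data: what it emulates and what it does not

The generator is the package's test bed, not a sequencing simulator.
It plants `n_mirnas` non-overlapping miRNAs (18–24 nt) on both strands
of a uniform-random toy genome, then emits exactly `library_depths`
reads per library: miRNA reads drawn multinomially from a fixed
abundance vector (equal weights by default — this makes expected fold
changes analytic), scaled by `2^log2_effect` for MN; a configured
fraction carries one uniform seed-position substitution; contaminants
are a uniform mix of adaptor dimers, low-quality reads, ≥10%-N reads
and adaptor-free random inserts, exercising each removal rule (the
source states no quality model, so this mix is a stand-in, not a
reconstruction). Qualities are Phred 30–40 for good reads and 2–15 for
low-quality ones. All randomness flows from one seed; identical
configurations give byte-identical outputs.

Two caveats matter when reading test results. First, fixed-depth
multinomial sampling renormalizes composition: planting effects `e_i`
makes the expected fold change `e_i + log₂(S_NC/S_MN)` with
`S = Σ w_i 2^{e_i}`, a small shared offset (≈ −0.06 log2 units in the
default recovery setup) — exactly the compositional coupling real
relative-abundance data has. Second, the generator has no sequencing
error model, no precursor structure and no rRNA/tRNA classes, so
passing tests demonstrate algorithmic correctness on clean ground
truth, not robustness to artifacts real libraries contain.

## Problem sizes and numerical choices

The validation suite runs at desk scale, chosen so the statistical
assertions have comfortable margins: planted-effect recovery uses 50
miRNAs at 10⁵ reads per library (counts ≈ 2000 per null miRNA put the
±0.3 recovery band at ≈ 3–6 binomial standard deviations), the type-I
simulation uses 200 miRNAs × 500 replicates at depth 10⁵ (10⁵
p-values), and determinism checks use small 3000-read runs. Report
rounding is half-up everywhere (one decimal for mapped percentages,
two for compositions, ratios and qPCR columns) with an epsilon guard
against binary representation artifacts; all comparisons and
classifications happen on full-precision values except the edit-ratio
classes, which are defined on the rounded ratio by design. Exact ties
in `dominant_base()` resolve in the fixed order A < U < C < G and are
flagged rather than hidden.

## Known limitations

* Exact-match mapping and counting only; isomiRs, NTA tails and
  shifted alignments are out of scope.
* One library per group: no dispersion modelling, and p-values from
  pooled libraries overstate certainty about *populations* — the
  statistic speaks about the libraries themselves.
* The edit analysis cannot distinguish genuine editing from genomic
  SNPs or sequencing error; it reproduces the ratio bookkeeping, not
  enzymology.
* The published top tables carry a handful of last-digit
  inconsistencies (fold changes whose printed inputs give a slightly
  different 7th–8th decimal); where that happens the package follows
  its own arithmetic and the bundled tables document the printed
  values.
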