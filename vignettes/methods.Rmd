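---
title: "Deriving and validating a therapy-induced secretome signature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and validating a therapy-induced secretome signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptisig)
```

## Overview

`ptisig` turns heterogeneous assay read-outs from a four-condition tumor
cell panel — parental (`P`), treatment-resistant (`PTR`), and their
IFNAR1-knockdown counterparts (`P_KD`, `PTR_KD`) — into a secreted,
type-I-IFN-regulated gene signature, and validates signatures by
average-CPM scoring and preranked gene-set enrichment. This vignette
documents the model assumptions, the tunable parameters, the numerical
conventions, and the places where the design was genuinely open.

## The expression stage

Counts are assumed to be gene-level non-negative integers with
library-size variation between samples. No dispersion estimation or
count-model testing is performed: effects are plain log2 fold changes of
group-mean CPM, because the downstream consumers (the ranked list for
enrichment, and the DE call feeding the signature rule) are defined on
fold changes, not on test statistics.

* **Filtering** keeps genes with raw-library CPM ≥ `min_cpm` (default 1)
  in at least `min_samples` samples (default: the smallest condition
  group size). The criterion is a declared convention, configurable at
  the call site.
* **Upper-quartile normalization**: per sample the factor is the 75th
  percentile of the *nonzero* counts divided by the library size,
  computed with `stats::quantile` type 7 (linear interpolation); factors
  are rescaled to unit geometric mean and the effective library is
  `library size × factor`. Restricting to nonzero counts keeps the
  quartile away from zero in sparse data; the geometric-mean rescaling
  makes CPMs comparable across runs while leaving within-sample gene
  ranks untouched (normalization is a per-sample scalar). An all-zero
  sample is a hard error naming the sample.
* **Fold change**: `log2((mean test CPM + c) / (mean ref CPM + c))` with
  pseudocount `c = 1` on the CPM scale (keeps the statistic finite; the
  value is a convention, not an estimate). The DE call is
  `|log2FC| ≥ τ_DE` with `τ_DE = 2`, boundary inclusive — thresholds
  printed as "≤ −2 or ≥ 2" include the boundary.
* **Ranked lists** contain *all* genes, ordered by metric descending
  with exact ties broken by lexicographic gene id (C locale, radix
  sort), so the ordering is bit-reproducible.

## The proteomic (cytokine-array) stage

Antibody arrays are run at n = 1 per condition with film read-out, so
the stage is deliberately non-inferential:

* **Exposure selection** picks, per target and membrane, the shortest
  exposure whose mean duplicate-spot volume exceeds the detection
  threshold while staying below the saturation ceiling. The default
  threshold is 3 × the membrane's mean background volume — a
  conventional signal-to-noise rule, overridable. Targets never
  detected are flagged and scored 0; targets detected only saturated
  use the shortest saturated exposure and carry a flag.
* **Quantification** subtracts the membrane's mean background volume,
  clamps at zero (physical non-negativity), and divides by the
  background-subtracted mean positive-control volume of the *same*
  membrane and exposure. This makes intensities invariant to
  membrane-wide gain, which is what exposure changes are.
* **Fold changes** use a small pseudo-intensity (default 0.01) so that
  undetected targets produce finite, directional ratios — never NaN.
  Direction is by sign outside a dead-band `eps` (default 0).
* Duplicate spots are summarized by the arithmetic mean.

Because n = 1, "significant" for array evidence means
`|log2 ratio| ≥ effect_floor` with a default floor of 0.58 (≈ 1.5-fold)
— a declared stand-in for the visual calls such arrays receive in
practice.

## The qRT-PCR stage

Relative expression uses the ΔCt rule with the housekeeping CT taken as
the arithmetic mean over the housekeeping genes (equivalently, a
geometric mean on the expression scale — the standard multi-housekeeping
practice). Cross-sample summaries are geometric means, because
expressions are ratio-scale.

Two conventions are provided. `"standard"` computes
`2^-(CT_gene - CT_HK)`, under which expression rises as the target's CT
falls — the textbook ΔCt rule. `"as_printed"` computes the exact
reciprocal `2^-(CT_HK - CT_gene)`, the literal reading of the formula as
it is sometimes printed in methods sections, under which expression
*increases* with the target's CT. The two are exact reciprocals and
fold changes are convention-covariant (switching convention inverts the
ratio); the package defaults to `"standard"` and surfaces the
discrepancy rather than guessing intent.

## Annotation

Secretome membership is a flat, closed-world list (emulating
GO:0005576, "extracellular region"): genes absent from the list are
non-secretory. IFN regulation is a local table of
(gene, IFN type, fold change, direction) records; a gene is
IFN-regulated iff at least one record has fold change ≥ `τ_IFN`
(default 1.5). No live database is queried — web-service results are
version-dependent and would break reproducibility. Summaries of IFN
regulation among DE genes count a gene toward the direction matching
its DE direction when it carries both up and down records, and report
per-type composition in two modes (`any`: a gene counts toward every
annotated type; `exclusive`: only single-type genes count), since
published summary percentages rarely state which mode they use.

## The integration rule

The signature is a pure conjunction over the evidence matrix, evaluated
per candidate:

1. membership in the preliminary list — secretory, IFN-regulated,
   transcript up in `PTR_vs_P` at `τ_DE`;
2. at least one significant proteomic record up in `PTR_vs_P`;
3. at least one significant record down in `KD_vs_PTR` — the type-I-IFN
   dependence check. Any modality is accepted by default because both
   the protein array and qRT-PCR probe the knockdown comparison in
   practice; a strict proteomic-only mode is available;
4. overall confirmation by at least one transcriptomic *and* one
   proteomic method. A weaker reading — "any two assays" — exists as
   `confirmation = "two_methods"`; the cross-modality reading is the
   default because it subsumes the weaker one whenever evidence spans
   both modalities.

Every conjunct can be disabled via `rule_config()`; removing a conjunct
can only grow the signature, and adding evidence rows never removes a
member — both properties are tested. The mirrored rule
(`derive_signature_down()`) flips every direction, and on any single
evidence matrix the up- and down-signatures are provably disjoint.
Signature ordering is alphabetical. Protein-to-gene mapping is an
explicit two-column table; unmapped targets are skipped with a warning
rather than fuzzily matched, because silent mis-mapping is worse than a
visible gap.

## Enrichment

The preranked statistic is the weighted running sum: hits gain
`|metric|^p / Σ_hits |metric|^p`, misses lose `1/(N - N_hits)`, and the
enrichment score is the extremum of maximal absolute deviation. Two
numerical conventions matter:

* **Tie-break**: when the positive and negative extrema tie in
  magnitude (common at `p = 0`, where the statistic depends only on hit
  positions), the negative extremum is taken, with a `1e-12` guard so
  accumulated floating-point error cannot flip the choice. At `p = 0`
  the statistic equals the classical Kolmogorov–Smirnov-style form and
  is invariant to strictly monotone metric rescaling; the test suite
  checks it exhaustively against a brute-force oracle over every
  hit-position configuration for universes up to 8 genes and sets up to
  3 members, and checks the weighted `p = 1` form against `fgsea` on
  random cases.
* **Default weighting** is `p = 1`, matching the cited tool family;
  `p = 0` is retained as the oracle-testable mode.

The null distribution per set is `n_perm` (default 1000) random
same-size gene sets drawn without replacement from the universe. Each
set has its own RNG stream seeded from (global seed, set index), so
adding or reordering sets does not reshuffle another set's draws. NES
divides ES by the mean |null ES| of matching sign; the q-value is the
sign-stratified ratio-of-tails estimator — the fraction of pooled null
NES at or beyond the observed NES over the fraction of observed NES at
or beyond it — clipped to [0, 1]. The conventional significance
read-out is q ≤ 0.25. Numerical agreement with any external GSEA tool's
FDR is *not* claimed: permutation FDR variants differ across tools;
internal consistency, determinism under a fixed seed, and oracle
equivalence of the statistic are what the package guarantees.

Signature scoring in expression data is the per-sample arithmetic mean
CPM over the set genes present (missing genes are reported), compared
between conditions by Welch's unequal-variance two-sided t-test. With
one sample on a side only the difference is reported; two constant
equal groups give p = 1 by convention.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
tested; it is not a tuning dial.

* **Counts**: negative binomial with `Var = μ + φμ²`, dispersion
  `φ = 0.2`, baseline log2 means uniform on [3, 10], per-sample
  library-size factors log-normal (SD 0.2) so normalization is
  non-trivial. Planted genes carry `log2FC = 3` in `PTR`, removed by
  the knockdown-reversal fraction (default 1) in `PTR_KD`. Defaults:
  2000 genes, 50 planted, n = 3 per condition.
* **Annotation**: secretome fraction 0.25 and type-I-up annotation rate
  0.3 for non-planted genes — rough genome-scale shares for an
  extracellular-region term and a permissive IFN-regulation database;
  every planted gene is secretory and type-I up at fold change ≥ 1.5 by
  construction.
* **Array**: exposures of 1, 4 and 16 s; signal spots scale linearly
  with exposure and clip at 65535 (film/detector saturation, which is
  what motivates shortest-exposure selection); background spots are
  constant film fog, so longer exposures genuinely rescue weak targets;
  per-spot log-normal noise (SD 0.1) is drawn once per physical spot
  and shared across re-exposures of a membrane.
* **qPCR**: one log2 unit = one cycle; two stable housekeeping genes;
  Gaussian technical noise, default SD 0.15 cycles, exactly noiseless
  at SD 0.
* **Seeding**: one global seed fans out to fixed per-assay child seeds,
  so changing one assay's structure never reshuffles another's draws;
  every generator is a pure function of (config, seed).

The generator emulates the *statistical* structure of the assays, not
their biology: no gene–gene correlation, no batch structure, no
isoform-level effects, no immune-cell mixtures, and condition effects
confined to the planted set. Passing tests therefore demonstrate that
the machinery recovers a planted signal under realistic noise — not
that any particular biological dataset would yield a particular
signature.

## Problem sizes and what the tests show

The recovery suite runs the full pipeline at the default conditions
over 50 seeds, and the enrichment read-out at 2000 genes with 1000
gene-set permutations over 20 seeds — sizes chosen so the whole suite
runs in minutes on a laptop while the Monte-Carlo rates are stable.

One property deserves honesty: under the default conditions the
*joint* event "all 50 planted genes clear |log2FC| ≥ 2" is statistically
out of reach. With dispersion φ and n replicates, the sampling SD of a
per-gene log2 fold change is bounded below by `sqrt(2φ/n)/ln 2 ≈ 0.53`
at φ = 0.2, n = 3 — even with infinitely deep counts — so each planted
gene at true log2FC 3 clears the threshold with probability ≈ 0.97 at
best, and typically one to three of the fifty miss in any given run.
The pipeline is conservative in the opposite direction: non-planted
false positives are rare, because a false entrant must jointly pass the
DE, secretome, IFN, proteomic and knockdown-reversal filters. Users
planning a real panel at n = 3 should expect the same asymmetry: the
rule's precision is high, its per-gene recall is bounded by count
noise at the DE threshold.

## Interfaces

All I/O is plain text: counts and sample tables as TSV, gene sets as
GMT, ranked lists as RNK, array spots as long-format CSV, CT tables as
TSV, configurations and run manifests as JSON. `validate_config()`
fills defaults, rejects unknown keys by name, and warns below 100
permutations; `run_pipeline()` executes the stages in dependency order,
records per-stage record counts and MD5 hashes of every artifact in the
manifest, and reproduces byte-identical outputs under a fixed
configuration (the manifest differs only in its timestamp). The
exported functions are the package's interface; no shell wrapper is
shipped, since every stage is a single function call.

## Known limitations

* The fold-change ranking carries no moderation or shrinkage; genes
  with tiny counts can rank high. The pseudocount damps but does not
  remove this.
* Array quantification trusts the spot volumes it is given; no image
  processing, spot finding, or inter-membrane calibration beyond the
  positive controls is attempted.
* The permutation FDR is a gene-set-permutation estimator; it does not
  model inter-gene correlation, and q-values across heterogeneous set
  sizes share one null pool per sign stratum.
* The evidence rule is set-logical by design: no meta-analytic
  weighting or p-value combination across assays is performed.
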