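---
title: "Selecting and encoding amino-acid properties: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting and encoding amino-acid properties: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raaindex)
```

## The problem

Databases of amino-acid scales assign each of the 20 standard residues one
measured biochemical or physical value per scale — hydropathy, polarity,
contact numbers, retention coefficients, and hundreds more.  Such collections
are attractive for turning protein sequences into numbers, but they are
unusable raw: many scales have missing values, and the collection is heavily
redundant (dozens of near-identical hydrophobicity scales).  `raaindex`
implements a selection pipeline that reduces such a collection to a small
informative subset, ships the resulting eight-property reduced table
(rAAindex), encodes aligned protein sequences with it, and quantifies how
much better the property encoding captures sequence-family diversity than a
same-width binary code.

## The selection model

The 20 residues are treated as the statistical units.  Each property is an
explanatory variable; the response is the binary hydropathy class of the
residue.  The pipeline has four stages:

1. **Completeness.** Properties with a missing value for any residue are
   dropped (`as_index_table()`).
2. **Correlation pruning.** While any retained pair has Pearson |r| above a
   threshold (default 0.85) over the 20 residue values, the pair with the
   highest |r| is found and the member with the larger mean |r| against the
   remaining properties is removed, ties broken by accession
   (`prune_correlated()`).  The procedure is deterministic and idempotent.
   The greedy order is a design choice: backward elimination is
   under-specified without one, and this rule removes the "most redundant"
   member of the worst pair first.
3. **Permutation importance.** `permutation_vim()` runs repeated
   random-forest trials.  In each trial one forest of `ntree` CART trees is
   grown on stratified bootstrap samples of the 20 residues.  A property's
   importance in a trial is

   $$\mathrm{VIM}(x_i) = \frac{1}{\mathit{ntree}}
     \sum_{t=1}^{\mathit{ntree}}
     \left( \mathrm{err}\widetilde{\mathrm{OOB}}_t - \mathrm{err
     \,OOB}_t \right),$$

   the mean over trees of the increase in out-of-bag misclassification
   *counts* when the property's out-of-bag values are permuted.  Properties
   a tree never splits on contribute exactly zero for that tree, so a
   constant property scores exactly zero.  Properties with positive mean
   importance are kept and ranked (`filter_by_mean_vim()`).  The standard
   deviation of the ranked scores is retained in the report for diagnostic
   plots; the operative filter is the positive-mean rule.
4. **Nested forward selection.** For each prefix of the ranking,
   `nested_selection()` fits `trials_per_step` fresh forests on the prefix
   and records the ensemble out-of-bag error percentage over the 20
   residues.  The selected subset is the longest prefix before the first
   step whose *mean* error exceeds `threshold_pct` (default 2.0%).  With 20
   units a single misclassification is 5%, so individual trials can only
   realize multiples of 5%; the threshold is therefore applied to the
   across-trial mean, which is fractional.  The 2% default reflects the
   regime in which at most a fraction of a residue misclassification is
   tolerated on average.

`reduce_pipeline()` composes the stages and reports retained/dropped counts
per stage.

### Forest engine

The forest is purpose-built (C++): binary classification of 20 fixed
samples, stratified per-class bootstrap, Gini splits grown to purity,
`mtry = floor(sqrt(m))` by default.  The narrow scope is deliberate — the
permutation-importance definition above needs per-tree out-of-bag counts
under explicit, reproducible bootstraps and permutations, which generic
forest libraries do not expose.  The engine's out-of-bag error was
cross-checked in the test suite against an independent forest
implementation on identical inputs, and its importance ranking against a
second engine's permutation importance.  Vote ties go to the overall
majority class; all randomness flows from one integer seed through
counter-derived streams (`splitmix64`/`xorshift64*`), independent of R's
global RNG, so identical seeds give bit-identical reports on any platform.

### Hydropathy labels

Published accounts of this kind of selection rarely print the residue
dichotomy they used.  The default here is explicit and pluggable:
hydrophobic = the seven residues with positive Kyte–Doolittle hydropathy
(A, C, F, I, L, M, V), hydrophilic = the rest (`hydropathy_labels()`).  The
scheme name is recorded in every report, and a custom 20-residue labelling
can be supplied as a data frame.

## The packaged reduced table

`raaindex()` returns the packaged eight-property reduced index (accessions
JACR890101, COWR900101, ZIMJ680103, MEEJ810102, FAUJ880110, WARP780101,
PONP800108, LIFS790102), transcribed verbatim from its published form.  Two
details are worth noting.  First, published annotation listings disagree on
the description strings of these accessions;
`raaindex_annotations()` therefore carries both variants and treats the
accession as the identifier.  Second, whether the printed numeric values
exactly match the current database entries for those accessions cannot be
established from the publication alone; the table is shipped as printed and
the golden tests pin every one of its 160 cells.

Re-running `reduce_pipeline()` on a current scale collection will generally
*not* reproduce the eight-property table or the historical stage counts
(544 → 531 → 283 → 93 → 8): those depend on the database snapshot and on
stochastic forest runs.  The pipeline's correctness is instead established
on synthetic tables with known planted structure (below).

## Encoding

`extract_block()` removes alignment columns whose gap fraction exceeds a
tolerance (default 0: strictly gap-free, since a homologous block is by
construction gap-free; any residual gaps under a laxer tolerance are imputed
by the column majority residue and logged).  `encode_bpp()` concatenates
each residue's property row from N- to C-terminus, giving an
`L × m` lattice per sequence; `encode_binary8()` is the baseline, mapping
each residue to the big-endian 8-bit expansion of its ordinal in the
canonical residue order.  The published baseline is described only as
"8-bit binary"; the ordinal code is chosen because it is injective,
dimension-fair against the eight-property table (both encode 8 numbers per
residue), and exported (`binary8_codes()`) so an alternative bit assignment
can be swapped in.  Family tags are metadata and never enter the encoding.

Whether the points entering the diversity analysis should be whole blocks
or sub-sequence fragments is ambiguous in published descriptions of this
kind of analysis (N-to-C "fragment" orderings are sometimes discussed
without a definition of the fragmentation).  `encode_set()` therefore
offers an optional sliding-window mode (`window`, `step`; CLI `--window`,
`--step`) that encodes overlapping fragments as separate rows, but it is
off by default and the packaged comparison operates on whole blocks.

## Diversity analysis

`run_pca()` performs covariance (center-only) PCA.  Correlation PCA is not
well-defined here: binary matrices contain constant columns (the three
high-order bits are zero for all ordinals below 32), and zero-variance
columns cannot be scaled to unit variance.  They are dropped and listed
instead.  This convention affects the absolute variance percentages one
obtains — published percentages computed under an unknown convention are
not directly comparable.  Eigenvector signs follow a deterministic
convention (largest-magnitude loading positive).  `compare_encodings()`
encodes one block both ways, runs PCA on each, and reports the PC1+PC2
variance percentages and per-family centroids; the package's claim is
directional — the property encoding explains at least as much leading
variance as the binary baseline on property-structured families — not a
reproduction of any particular percentage.

## Synthetic data: what it emulates and what it does not

`gen_index_table()` builds property tables with planted truth: informative
columns with unit within-class standard deviation and class means
`label_gap` apart (a Cohen's-d effect size; default 2), redundant copies
tuned to a target correlation (default 0.9) with their parent, and
label-independent standard-normal noise (default 50 columns).  Under this
construction two distinct informative columns share only the label
component, so their mutual correlation (≈ 0.48 at the defaults) stays well
below the within-group redundancy, and the planted redundancy structure is
identifiable — the alternative of scaling columns to unit *total* variance
at the same nominal gap would make every label-aligned column correlate at
≈ 0.91 with every other and the pruning stage would collapse the planted
groups outright.

`gen_family_alignment()` draws per-family consensus sequences and mutates
each site i.i.d.  In `property_structured` mode, family consensi are offset
in the standardized property space of a reference table and substitutions
prefer property-near residues through a softmax over negative Euclidean
distance (temperature 1 by default); `uniform_random` mode is the null.
The default scale (4 families × 70 sequences × 28 columns) mirrors a
283-sequence, 28-residue study set.  The generators emulate controlled
divergence only: no phylogeny, no indel process beyond injectable gap
columns, no site-rate heterogeneity.  Tests passing on these fixtures
demonstrate that the machinery is correct and directionally sensitive, not
that any particular real protein family will behave identically.

## Known limitation: the 2% threshold versus pruning

One structural property of the pipeline deserves emphasis.  The nested rule
admits a prefix only if *every* sub-prefix, starting from the single
top-ranked property, keeps mean error at or below the threshold.  At a 2%
mean over 20 residues this demands that the top property alone classifies
nearly perfectly.  But a label-aligned column that classifies nearly
perfectly necessarily shares most of its variance with the label, and any
two such columns are then mutually correlated above typical pruning
thresholds — so the pruning stage removes them as redundant before the
nested stage can see them.  Consequently, on synthetic tables with several
*independent* planted signals of moderate effect size (Cohen's d ≈ 2), the
first nested step typically shows error far above 2% and the selection
aborts as empty; full multi-group recovery at the default threshold is not
achievable, and the corresponding stochastic acceptance check in the test
suite documents this honestly rather than loosening the threshold.  On
property collections like the real database — where the label *is* derived
from scales present in the collection, and near-perfect single classifiers
exist — the rule behaves as published.  Users who want multi-signal
recovery on weaker planted structure should raise `threshold_pct`; the
parameter is exposed everywhere.

A related statistical note: with the property table held fixed, the mean
importance of one noise column over many trials converges to a per-table
conditional constant of order ±0.005 count units, not to zero; only across
fresh noise draws is the permutation importance unbiased (an
unconditional-unbiasedness property test covers this).  Confidence bands
built from the trial spread alone will therefore eventually exclude zero
for a fixed table, however correct the implementation.

## Problem sizes and tolerances

Simulation-backed checks in the test suite use deliberately chosen sizes:
forests of 50–100 trees, 10–30 importance trials, 10–25 forests per nested
step, 20–50 generator seeds per stochastic claim.  These sizes put every
stochastic assertion comfortably away from its pass boundary while keeping
the whole suite quick to run; the exact values are stated in the tests.
Exact oracles (the one-tree importance count, the printed table cells)
are asserted identically; eigendecomposition comparisons use 1e-8;
variance-fraction sums 1e-9.  Degenerate inputs fail fast with typed
errors: single-class labels, empty selections at the first nested step
(with the diagnostic curve attached), all-gap blocks, all-zero-variance
matrices.

## Reproducibility

Every stochastic function takes an explicit seed (via `rf_config()` or the
generator specs) and documents its stream usage; identical seeds give
identical results byte for byte.  The command-line interface
(`raaindex_cli()`, installed as `exec/raaindex`) writes a provenance JSON
sidecar (inputs, parameters, seed, package version) next to every output
and refuses to overwrite without `--force`.
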