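---
title: "envchip: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{envchip: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(envchip)
```

envchip implements the analytical backbone of an environmental
functional-gene expression microarray: designing short oligonucleotide
probes against annotated microbial genes, screening them for
cross-hybridization, and analyzing the probe-by-sample intensity
matrices a seasonal field campaign produces. This vignette explains the
models, the tunable parameters and their defaults, the numerical
choices, and what the synthetic-data generators do and do not emulate.

## Duplex thermodynamics and the mismatch rule

Perfect-duplex melting temperatures come from the unified DNA/DNA
nearest-neighbor table with duplex-initiation terms, the entropy salt
correction 0.368 (L-1) ln[Na+], and the two-state van't Hoff
expression with total strand concentration C~T~ (C~T~/4 for
non-self-complementary duplexes). Defaults are 50 mM monovalent cation
and 100 nM total strand; both are exposed through
`duplex_conditions()` because array vendors rarely publish the
conditions their design software assumes. Tm is carried at full double
precision internally; rounding happens only in reports.

Mismatched duplexes use a deliberately simple model: each 1% of
mismatched positions costs 1 degree Celsius of Tm, independent of
mismatch identity and position. Three mismatches in a 35-mer therefore
cost 8.571 degrees (quoted as 8.5 after truncation to one decimal).
This linear rule, not a position-weighted thermodynamic model, is the
basis of the specificity screen, because empirically three mismatches
under array hybridization conditions depress signals to background —
equivalent to at least a 15 degree separation. `adjusted_duplex_tm()`
is consequently exact bookkeeping: perfect Tm minus the penalty for
the Hamming distance.

**Uniqueness rule.** A probe is specific if every same-length window of
every nontarget sequence (both strands by default, since labeled cDNA
targets are effectively double-stranded) melts at least 15 degrees
below the perfect duplex. A separation of exactly 15.0 degrees is
kept ("at least"). rRNA decoys are always part of the nontarget set
and rejections they cause are reported with their own reason code,
because rRNA dominates environmental RNA and cross-reaction with it
drowns mRNA signals. The window scan is exhaustive (C-level
mismatch-bounded matching from Biostrings). We deliberately did not
use a seed-word prefilter: offenders at the 15-degree boundary can
carry evenly spaced mismatches that leave no exact seed of useful
length, so seeding is not behavior-equivalent to the full scan.

**Sequence-quality screens.** Hairpin stems of at least 6 bp closed by
loops of 3-8 nt, homopolymer runs above 6 nt, and tandem dinucleotide
repeats above 5 units disqualify a window; all three thresholds are
configurable and were chosen as values typical for array-probe design.
One observation keeps the hairpin screen cheap and exact: a stem
longer than the minimum with an in-range loop always contains a
minimum-length stem (its innermost base pairs) with the same loop, so
scanning stems of exactly the minimum length decides the verdict.

**Candidate enumeration and selection.** All sense-strand windows of
lengths 35-45 nt with Tm in a 70-75 degree window pass to the
uniqueness filter; survivors are picked greedily per gene by closeness
of Tm to the window midpoint (ties to the leftmost start), enforcing
non-overlap. Per-gene stage counts and per-reason rejections are
returned so that enumerated = kept + rejected reconciles exactly.

## Cross-hybridization screening

`local_search()` is an exhaustive ungapped local aligner: for every
probe, subject and strand it finds the maximal-scoring segment on each
alignment diagonal (match +1, mismatch -2 by default) and reports
segments above a raw score floor. E-values follow the Karlin-Altschul
extreme-value model E = K m N exp(-lambda S) with lambda solved from
the scoring system under uniform base composition and the search space
taken as probe length times total database length. Ungapped alignment
is appropriate at probe scale, where the hit criteria allow at most a
handful of mismatches; a gapped mode is out of scope. Hits are then
filtered on the screening criteria: alignment length at least 30 nt,
E below 0.05% (read as 5e-4), and alignment identity at least 90%.
For a 35-nt probe those criteria imply at least 27 perfectly matched
positions, up to 8 mismatched probe positions, and at least 77%
overall identity (`crosshyb_criteria()`); alignment identity and
overall identity are kept as distinct fields because both appear in
specificity reporting.

Hit-count classes (none / single / double / multiple) and
taxonomic-rank classes (all hits from the probe's genus; from its
family; some outside the family, with an outside-phylum flag) mirror
the standard specificity tables. Hits lacking taxonomy are excluded
from rank comparison and counted separately, since environmental
databases are incompletely annotated. Reported percentages round
half-up to one decimal; `ceiling()` calls that implement "at least x%
of L positions" subtract 1e-9 first so binary representation of 0.90
cannot inflate the requirement.

## Expression pipeline

The pipeline follows the standard array workflow. Duplicate
hybridizations are averaged after confirming concordance
(`replicate_concordance()` reports squared Pearson correlation of log
signals and the fraction of probes outside the 2-fold band). Quantile
normalization forces all sample columns onto the row-wise mean of the
column-sorted values; ties receive the mean of the quantile values
they straddle (the most common dialect — documented because dialects
differ, and with ties the "identical column distributions" property
holds only up to tie-averaging).

The background is global, not per-array: all normalized values are
pooled and the background mean is the mean of the lowest 5%. The
matching standard deviation is, by default, the SD of that same lowest
subset — the only self-contained reading of "background plus 3 SD" —
with `sd_scope = "all"` exposed as the alternative. A probe is called
expressed when it strictly exceeds mean + 3 SD in at least two
samples. Heat values are log2 of signal over background, floored at
zero.

Differential expression is measured against seasonal freshwater
baselines: per season, the mean of the two river (0 PSU) baseline
samples, with the metadata validator enforcing exactly two baselines
per season. Intensities are clamped at the background mean before any
log ratio (a value below the optical background is measurement floor,
not biology; clamp events are counted). Probes with |log2 ratio| of at
least 1 in at least two non-baseline samples are selected — inclusive
at the boundary, both directions jointly, since seasonal studies show
both up- and down-regulation; an exactly zero ratio never qualifies,
which makes `fold = 1` mean "changed at all in two samples".
Upregulated cluster sets use the strict one-sided version. Rollups
report per-phylum medians over expressed probes as fold changes over
the global median, per-family percentages of gene sets (families under
15 probes array-wide fold into "other"), Spearman sample correlations,
and a per-probe one-way fixed-effects ANOVA (`stats::oneway.test`,
equal-variance) at raw P < 0.001 with no multiplicity correction by
default (a Benjamini-Hochberg option exists but is off, matching how
such filters are conventionally reported); probes with zero variance
are guarded to NA and never selected.

## Clustering

Gene and sample trees use correlation distance (1 - r, centered by
default; the uncentered variant is exposed because heat-map tools
offer both) under agglomerative complete linkage. Complete linkage is
implemented directly rather than delegated, because two behaviors are
pinned down that generic implementations do not guarantee: ties at the
minimal distance merge the pair containing the smallest leaf *label*
(labels, not positions, so results are deterministic *and* invariant
under input permutation — duplicated profiles produce exact zero-
distance ties where position-based rules would be order-dependent),
and leaves are ordered recursively with the tighter subtree first
(height ties again broken by smallest label), which fixes heat-map
appearance. `stats::hclust` serves as an independent cross-check on
tie-free instances in the test suite, and a naive O(n^3) oracle checks
the merge sequence with ties. Trees export as Newick (via ape) and as
Cluster-3.0 CDT/GTR/ATR triples for heat-map viewers.

## Synthetic data

The generators produce every input the toolkit consumes, with planted
ground truth, so the whole pipeline can be validated end to end
without field data.

`simulate_community()` builds one homologous gene set per phylum on a
three-level star phylogeny (phylum root, family bases, genus bases,
genes). Substitutions are uniform over positions and bases with no
indels, so identity bookkeeping is exact Hamming arithmetic. Branch
substitution probabilities are solved so that the *expected pairwise
identity between genes* equals the requested level at each taxonomic
distance (defaults 0.95 within genus, 0.85 between genera of a family,
0.70 between families of a phylum; different phyla are unrelated),
using the uniform-resampling channel identity
t = 1/4 + 3/4 (1-u)(1-v). The defaults make within-genus homologs
cross-hybridize (as real close homologs do) while cross-family genes
stay separable — designing on such a community demonstrates both
rejection and retention paths. `simulate_rrna()` draws decoys around a
conserved core (target pairwise identity 0.90, comfortably above the
0.80 floor).

`simulate_study()` emulates the shape of a four-season field campaign:
4 seasons x 16 samples, two river baselines per season, the rest
spread over estuary/plume/ocean habitats with plausible salinities.
Signals follow the additive optical model
*intensity = background floor + target abundance*: an array cannot
report less than its optical background, and modeling this explicitly
matters — a purely multiplicative model lets down-regulated values
fall into intensity regions no baseline sample occupies, which
quantile normalization then distorts. Expressed probes (90% by
default) draw a continuous log-normal abundance, 2^N(3.5, 1.5) times
the floor; unexpressed probes sit exactly at the floor, so at zero
noise the expressed flag is exactly recoverable from the
background + 3 SD call. Differential effects (a 4-fold change, up or
down, in one season's non-baseline samples) are planted on 20% of the
clearly expressed probes — abundance at least 4x the floor — because a
fold change on a probe at the optical floor is unobservable by
construction. Noise is multiplicative log-normal with SD 0.2 log2
units, the standard array error model. All generators are
bit-reproducible per seed.

What the generators do *not* emulate: per-array scale or dye biases
(the simulated arrays are already commensurable, so quantile
normalization is exercised as a near-identity idempotent step rather
than as a correction), spatial artifacts, probe-specific affinity
differences, indel evolution, and chimeric sequences. Passing the
recovery suite therefore shows the statistics are implemented
correctly and calibrated under the stated error model — not that the
pipeline overcomes artifacts it never sees.

## Validation sizes and observed behavior

The test suite checks every statistic against independent brute-force
oracles on seeded fixtures (quantile normalization, background,
expression calls, differential selection, complete linkage, local
search; 20 fixtures each at 60-80 probes x 6-8 samples, 9-12 leaf
trees, and 2-4 sequence databases), and runs the end-to-end recovery
experiment at 300 probes x 64 samples x 20 seeds — sizes chosen so the
full suite runs in minutes on one CPU while keeping every binomial
check well-powered. The planted-truth experiment requires pooled
sensitivity of at least 0.95 and pooled FDR of at most 0.05 for
4-fold effects at noise SD 0.2; the ANOVA null calibration at
alpha = 0.001 over 10,000 probes must land inside the binomial 95%
band. `scripts/acceptance.R` reruns these same computations from
scratch at an arbitrary seed and writes the measured values as JSON.

## Known limitations

- The mismatch penalty ignores mismatch identity, position and
  tandem-mismatch effects; it is the screening model, not a
  thermodynamic truth.
- E-value calibration (the constant K) is nominal; the tests only
  verify that nominally significant hits against random sequence are
  appropriately rare.
- The uniqueness scan is exact but quadratic in total sequence length;
  genome-scale nontarget sets would want an indexed prefilter with a
  guaranteed mismatch bound, which is future work.
- `anova_filter` fits fixed effects only; no batch or mixed-effects
  structure.
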