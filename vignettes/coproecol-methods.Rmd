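---
title: "Methods and design notes for coproecol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for coproecol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coproecol)
```

`coproecol` reconstructs the diet and deposition history of an extinct
herbivore from a coprolite series using four semi-independent proxies:
pollen assemblages, plant macrofossils, short ancient-DNA amplicons, and
radiocarbon dates.  This vignette explains the statistical model behind
each stage, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, and the design decisions that were
genuinely open.

## Pollen summaries

Percentages are computed against the *pollen sum*: the per-coprolite total
over in-sum taxa.  The packaged convention is that all terrestrial pollen
and fern/lycophyte spores are in-sum, while the exotic spike (added to
measure concentrations) and coprophilous fungal spores such as
*Sporormiella* (a dung indicator, not vegetation) are out-of-sum; an
out-of-sum column is still expressed relative to the sum, the standard
pollen-diagram convention.  Counting standard is at least 250 grains per
sample; the constructor flags lower totals.  Reported percentages round
half-up to one decimal, matching the usual published precision — note base
R's `round()` is round-half-even, so the package carries its own
`round_half_up()`.

Concentration uses the exotic-spike ratio estimator
`(count / spike_observed) · spike_total / mass_g` (grains per gram), which
is undefined when no spike grains were counted; that case is an error, not
a zero.  Organic content is loss on ignition, `100 · (dry − ash) / dry`.

## The environmental prevalence index and its null

Pollen reaches a dung bolus both through diet and through the ambient
pollen rain, and taxa differ enormously in how much pollen they shed.  The
EPI summarises that expectation as the product of three ordinal scores —
pollination mode (wind 3, animal 1), pollen production (1–3) and
dispersability (1–3) — giving values in [1, 27].  The factor scores come
from regional palynological reference works and are a *user input*; the
package ships only an editable template (`epi_factor_template()`), not
asserted values, and taxa without scores are dropped from the analysis via
the registry's `epi_include` flag.

The published method plots observed abundance rank against EPI and reads
taxa above/below a "null (cumulative frequency) distribution line" as
over-/under-represented, without giving the line a formula.  The package
operationalises it as: the expected rank of a taxon is its tie-averaged
rank when taxa are sorted by EPI descending — exactly the cumulative count
of taxa with higher EPI plus the average position within the tie class.
This is an *interpretation*, stated prominently: it reproduces the reading
"abundance directly related to environmental prevalence ⇒ on the line",
and makes the classification depend only on ranks (so it is invariant to
any monotone transform of the summed percentages).  At the default margin
0 a taxon is neutral only when the two ranks coincide; because the
published method is explicitly a visual, "somewhat subjective" guide, an
optional permutation margin (`epi_permutation_margin()`) is provided but
off by default.

## Assemblage clustering

Profiles are clustered on percentages (not raw counts).  The historical
gene-expression clustering programs whose defaults the published analysis
used worked with the *uncentred* Pearson correlation,
`s(x, y) = Σxᵢyᵢ / (‖x‖‖y‖)`; the distance is `1 − s` with range [0, 2],
0 for identical profiles and 1 for profiles on disjoint taxa.  Both the
metric and the linkage (average, by default) are overridable.
Agglomeration is implemented in the package with a documented
deterministic tie-break — among equal minimum distances the pair with the
lowest cluster-creation indices merges first — and the result is
`hclust`-compatible, so `cutree()` and `plot()` work.  The unit tests keep
a dual route: the package's own quadratic-scan agglomeration is checked
against `stats::hclust` on random instances.  "Highly similar" groups are
a cut at distance 0.1 (correlation ≥ 0.9), exposed as a parameter; the
choice is a reading of what "nearly identical assemblages" means on a
correlation scale, not a fitted threshold.

## Ancient-DNA assignment

**Depositor calls.** The 31 bp mitochondrial control-region fragment is
compared to every reference by Hamming identity (positions involving N are
excluded from numerator and denominator).  Several species tying at the
best identity is a legal outcome reported as *ambiguous* — a fragment this
short genuinely cannot separate all species pairs.  The haplotype is the
base at diagnostic position 25.  A call is *damage-consistent* when the
query differs from some reference only by C↔T substitutions, the signature
of post-mortem cytosine deamination; distinguishing genuine haplotype
variation from damage is then an argument about geographic consistency and
replication across samples, which is exactly what the deposition-event
module provides.

**Dietary clones.** Each 95 bp rbcL clone is aligned semi-globally (clone
global, reference local) against full-length references; scores default to
match +1, mismatch −1, gap −2 — the scheme is not fixed by the source
method and is fully configurable.  Identity is matches over aligned
columns; a clone is assigned when identity exceeds 96% *and* its
translation in the reference reading frame contains no internal stop codon
(a stop in the trailing partial codon does not count).  The best reference
is reported even for unassigned clones.  For speed, exact substrings are
resolved by pattern matching and substitution-only variants by a
mismatch-tolerant search before the dynamic-programming fallback; for
substitution-only damage these routes give identical results.  This
nearest-reference design deliberately replaces Bayesian phylogenetic
placement: it is deterministic, desk-scale, and the strong agreement
between similarity-based and tree-based identifications reported for this
kind of data makes the simplification defensible.  It cannot, however,
place a clone that matches no reference closely — such clones simply
remain unassigned.

## Radiocarbon calibration

A measurement `cra ± σ` is calibrated against a user-supplied curve
(calendar knots, curve ¹⁴C age, curve error; linear interpolation) by
evaluating `p(θ) ∝ exp(−(cra − µ(θ))² / 2(σ² + σ_curve(θ)²))` on a 1-yr
grid and normalising to mass 1.  The grid covers every calendar age whose
curve value is within 6 combined σ of the measurement, extended 6 σ
outward, so multimodal posteriors on wiggly curve sections are retained.
The 95.4% highest-density region accumulates years in decreasing density
order until the mass reaches the level, then merges them into maximal
contiguous intervals — by construction the region's mass is ≥ 0.954 and
dropping its least-dense year takes it below.  Intervals are reported as
integer cal BP, older bound first.  Published ranges may be rounded to
5 yr by other software; comparisons should allow ±10 yr.  The likelihood
deliberately omits the `1/σ_tot(θ)` prefactor some programs include: the
build contract specifies the plain Gaussian kernel, and where curve errors
vary slowly the difference is negligible.  No curve ships with the
package; any `.14c`-layout file loads, and `identity_curve()` provides the
analytic surrogate used throughout the tests (calibration then reduces to
a Gaussian whose 95.4% interval is the ±2σ interval — the property the
test suite checks to grid precision).

## Deposition events and MNI

Two coprolites join one defecation event iff they share an assemblage
group AND their haplotypes do not conflict AND their calibrated ranges
overlap, where missing evidence is permissive (an undated or unhaplotyped
coprolite cannot veto).  Events are the transitive closure of that
relation; the closure may chain through an undated coprolite (documented
liberal behaviour, disabled by `strict = TRUE`, which demands both sides
of every joining pair be haplotyped and dated).  One subtlety found by the
property tests: naive closure could chain two *conflicting* haplotypes
through an unhaplotyped intermediate, so the union-find tracks a
component-level haplotype and refuses any union that would mix two
non-missing haplotypes — conflicting haplotypes split groups, never merge.

Events link into *probable individuals* under a stricter rule: both events
must carry the same non-missing haplotype and their consensus age ranges
must overlap (the "same bird on a different day" reading).  Missing
evidence never links.  MNI is the number of individual groups; it is
bounded below by the number of distinct haplotypes and above by the number
of coprolites, and event partitions always refine individual partitions.

## The synthetic generator

`simulate_dataset()` emulates the stated world end to end: `n_individuals`
birds (default 5, the minimum the motivating deposit implies), each with a
Dirichlet(0.3) diet over a random 8-taxon subset of 50 taxa (individuals
in such deposits show individual-specific assemblages; small concentration
gives a few staples); 3 events per bird × 2 boli per event ≈ 30 coprolites
(multi-bolus events are attested; the events-per-bird count is a free
choice, as the source only says "at least four" coprolites were
multi-bolus); pollen counts multinomial at depth 250 with expected
proportions `(1 − w)·diet + w·rain`, `w = 0.3` and rain ∝ EPI; an
out-of-sum *Sporormiella* column present in ~37% of samples; two
mitochondrial haplotypes differing by C/T at position 25, constant within
bird, amplifying with probability 33/35; clone libraries on the first 12
coprolites, dropping out with probability 1/3, of 16–52 clones drawn
multinomially from the bird's diet, with per-site C→T damage at 0.01
(internal stop codons then arise naturally); and event ages uniform on
700–6,400 yr BP *conditional on* a minimum pairwise separation (200 yr by
default — accumulation in such deposits is slow and punctuated), measured
as the curve value plus Gaussian(0, 30 yr) noise.  All draws flow from one
seed; datasets are byte-identical across runs.

What the generator does **not** emulate: gizzard grinding, differential
digestion, taphonomic loss beyond simple dropout, terminal-overhang damage
gradients, PCR chimeras, or real reference databases (references are
codon-safe random genes with guaranteed window divergence between taxa).
A green recovery test therefore establishes that the pipeline inverts
*this* generative model, not that it is robust to every artefact of real
ancient DNA.

Fields added to the configuration beyond the core world (`n_haplotypes`,
`diet_low_epi`, `min_age_separation`, `n_dna_samples`,
`moa_success_prob`, `diet_subset_size`) exist to express the worlds the
recovery properties describe — e.g. the MNI-recovery property plants one
well-separated event per bird with a distinct haplotype each, and the
cross-proxy property plants dietary taxa with low EPI factors (animal-
pollinated herbs) so that genuinely eaten, triple-proxy-detected taxa must
surface as over-represented.

## Numerical choices and degenerate inputs

Half-up rounding everywhere percentages are reported; zero pollen sums,
zero-spike concentrations, ash > dry masses, out-of-curve-range CRAs,
non-IUPAC queries, wrong fragment lengths and empty reference sets are
errors naming the offending input, not silent NAs.  Clustering tie-breaks
are lowest-index-first; rank ties are tie-averaged on both the observed
and the expected side, which is what makes "abundance exactly proportional
to EPI ⇒ every call neutral at margin 0" an identity rather than an
approximation.

## Known limitations

The EPI null is an interpretation of a figure-defined method; the
assignment module is only as good as its reference set; calibration does
no reservoir correction or multi-date modelling; MNI is a minimum, not an
abundance estimate; and the liberal event closure can over-merge through
undated specimens (use `strict = TRUE` to bound the other way).  No
empirical claim is made in this vignette that the test suite and
`scripts/acceptance.R` do not themselves compute.
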