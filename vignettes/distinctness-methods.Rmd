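---
title: "Methods: genomic and morphometric distinctness analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genomic and morphometric distinctness analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phocidist)
```

## The problem

A small, geographically isolated pinniped population — the motivating
case is a land-locked lake seal — may be either a recent offshoot of a
widespread marine species or a lineage with much deeper independent
history. `phocidist` bundles the three complementary lines of evidence
used to separate these hypotheses: (i) sharing of derived alleles among
populations, (ii) time-resolved gene-flow summaries from
isolation-with-migration (IM) model output, and (iii) diagnosability
from skeletal (dental) and soft-tissue (tongue) morphometrics. Every
stage can be exercised on bundled synthetic data with known truth.

## SNP filtering chain

Genotypes enter as diploid dosages of the VCF ALT allele. The chain is
`polarize → apply_masks → filter_missing_invariant → thin_variants →
maf_filter`, and each step is idempotent:

* **Polarization.** The ancestral allele at a site is the allele carried
  homozygously by *all* called outgroup individuals; sites with
  heterozygous, discordant, or entirely missing outgroups are dropped.
  Dosages are recoded to derived-allele counts and outgroup columns
  removed. Partial outgroup missingness is tolerated (unanimity among
  called individuals suffices).
* **Masks.** A 1-based site position `p` is inside a 0-based half-open
  BED interval `[start, end)` iff `start < p <= end`. A site is kept
  iff it is inside the positive (callable) mask and outside the repeat
  mask. Mask chromosomes unknown to the variant table draw a warning
  and are ignored.
* **Missingness / invariance.** A site is dropped when its missing
  fraction over individuals is strictly greater than `max_missing`
  (default 0.10 — so 5 missing of 46 individuals, 10.87%, is dropped
  while 4 of 46 is kept), or when all called dosages are equal.
* **Thinning.** Greedy left-to-right scan per chromosome keeping a site
  iff it is at least `min_dist` bp (default 1000, boundary inclusive)
  from the last kept site. The scan is deterministic; no seed is
  involved.
* **Derived-count (MAF) filter.** Keep a site iff its derived count is
  at least `ceiling(maf * 2N)` with `N` the *total* number of ingroup
  diploids (default MAF 0.05; with N = 46 the minimum passing count is
  5 of 92 chromosomes). The threshold is deliberately computed on total
  chromosomes, not called ones, matching the "5 among 92" formulation;
  `called_denominator = TRUE` switches to per-site called chromosomes.
  "MAF" here means *derived*-allele frequency: the five-of-92 rule only
  makes sense on polarized counts, so the folded interpretation is not
  used.

## Private-pattern statistics and PCA

For a chosen subsample (n individuals per population), a site's
*pattern* is the vector of presence bits — whether any sampled
chromosome of each population carries the derived allele. The
private-pattern proportion of a population is the fraction of sites,
among those with at least one presence bit in the subsample, whose
pattern is unique to it. Replicate subsamples (default 20, seeded,
drawn independently per n rather than nested) give a mean and SD. The
denominator choice (segregating-in-subsample) is one of two defensible
readings; `denominator = "all"` divides by all filtered sites instead.
Both shrink as n grows; the *expected decrease with n* is a property
the test suite checks.

Fixed private alleles require every called focal chromosome derived and
no non-focal chromosome derived; `either_allele = TRUE` also counts
focal fixed-ancestral against derived-fixed backgrounds.

PCA follows the covariance convention of smartpca with normalization
turned off: individuals × sites dosage matrix, per-site mean imputation
of missing dosages, column mean-centring, *no* variance scaling, SVD.
Sign is fixed per component by making the largest-magnitude loading
positive. A one-axis silhouette (`pc_silhouette`) quantifies focal
separation on PC1.

## Windowed genome trees

Windows of 1 Mbp separated by 0.5 Mbp gaps start at offset 0 on each
chromosome (the phase is configurable; nothing in the procedure pins
it), and trailing partial windows are discarded. Within a window,
sites with any missing genotype are excluded; each individual
contributes one haploid allele per site — the allele itself for
homozygotes, a uniform draw for heterozygotes (seeded). Sites whose
sampled alleles coincide are moved to the invariant tally, and the
mask-based invariant count is `masked bp − variable sites after
sampling`, which an inconsistent mask turns negative (an error, not a
silent clamp).

The bundled tree builder is neighbour joining on normalized Hamming
distances diluted by the invariant count
(`mismatches / (variable + invariant)`), with taxa pre-sorted by label
for deterministic tie-breaks, negative NJ branch lengths clamped to
zero and zero-length internal edges collapsed. This is an explicit
stand-in: it is *not* equivalent to ascertainment-corrected
maximum-likelihood inference, and externally inferred newick tree sets
are accepted as first-class input wherever trees are consumed.

Support summaries sample up to 500 trees without replacement (seeded),
root each on the outgroup's attachment edge (multi-taxon outgroups:
the edge above their MRCA; non-monophyletic outgroups skip the tree
with a log entry), prune the outgroup, and report the fraction of
trees in which the focal taxon set is exactly a clade's leaf set, plus
per-clade frequencies with a strict majority flag (> 0.5).

## Cumulative migration probability and split-time proxies

For a pair of individuals from two populations with symmetric
piecewise-constant migration rate `m(t)` (per generation, time running
into the past), the probability that their ancestral lineages have
exchanged by time `t` is

\[ M(t) = 1 - \exp\!\Big(-\int_0^t 2\,m(u)\,du\Big), \]

with the within-segment form
`M(t) = 1 − (1 − M_i) e^{−2 m_i (t − t_i)}`. The IM literature the
format comes from does not print the formula; if an input file carries
a published `M` column, that column is compared against the
recomputation and the maximum absolute deviation reported as a
diagnostic. Threshold times are exact within-segment inversions
`t* = t_i + ln((1 − M_i)/(1 − θ)) / (2 m_i)`; thresholds never reached
are flagged, never extrapolated. Trajectories can be truncated at the
M = 0.999 crossing for plotting parity with published figures.

Time units: boundaries below `1e-2` are auto-detected as
mutation-scaled and divided by μ (default 1.826e−8 per site per
generation) to get generations; years = generations × g (default
g = 10 y, so a scaled time of 1.826e−8 is exactly one generation =
10 years). `m` is always read per generation. Interior inversion (not
right-boundary snapping) was chosen for threshold ages. Pair
aggregates are arithmetic means and sample SDs (n−1) over
individual-pair replicates of the same population pair, excluding —
and counting — not-reached replicates.

## Morphometrics

Analyses use the four right lower postcanines P2, P3, P4, M1. A
specimen enters a measure family (length, height, angle, cusp count)
only if that measure is present for all four teeth; specimens with
dental anomalies are excluded; non-right-side rows are ignored with a
log note.

* **Permutation tests** on differences of group means are one-tailed.
  Below 20,000 label arrangements the null is enumerated exactly
  (ties count as extreme); above, a seeded Monte Carlo with the +1
  correction `p = (1 + #extreme)/(1 + B)`, default B = 10,000.
* **ROC/AUC.** Orientation is handled by negating scores when smaller
  values indicate positives (tooth lengths, top-cusp angles, M1/P4
  ratios). AUC is the Mann–Whitney concordance with ties at ½. The
  diagnostic cutoff maximizes Youden's J (the source analyses say only
  that the cutoff is "indicated by the ROC curve"; J is the standard
  objective choice and the rule name is recorded in the output), with
  ties broken toward higher sensitivity and the reported boundary
  placed midway between adjacent distinct scores. Ratio classification
  is boundary-inclusive: `ratio <= 0.88` is positive.
* **Crown geometry.** Relief = outline arc length over the crown
  divided by the base chord; computed in a base-aligned frame so it is
  invariant to rigid motion and uniform scaling. The top-cusp angle is
  measured at the highest apex between its two neighbouring apices and
  needs at least three cusps. The cusp index standardizes relief by
  relative crown height (max perpendicular height / base chord); the
  original index definition lives in cited comparative-dentition work
  not reproduced here, so this standardization is a documented
  placeholder and cross-study comparisons of its values should be made
  with care. "Maximum height" is measured perpendicular to the base
  chord (not the cervix), another convention choice.
* **Tongue profiles.** The axis is the tip-to-posterior-body chord;
  widths are measured perpendicular to it at the stations 10%–100% in
  ten-percent steps and normalized by the maximum measured width. The
  broad-tip flag (suction-feeder-like) fires when the relative width
  at the 20% station is ≥ 0.70. The type contract fixes ten bins with
  a defined 20% station, so widths are evaluated at bin right edges;
  an alternative reading (bin midpoints) would shift stations by 5%
  and was rejected as incompatible with the 20%-station criterion.

## The synthetic-data generators

The generators emulate the *shape* of the real inputs, not their
provenance; no generative model for the original data exists, so all
choices here are explicit stand-ins.

* **Genotypes.** An ancestral derived-allele frequency per site is
  drawn from Uniform(0.05, 0.95) (boundary fixation would otherwise
  dominate private-allele counts), then propagated down a rooted
  population tree: each branch with drift coefficient `F ∈ [0,1)`
  replaces `p` by a Beta draw with mean `p` and variance
  `F·p(1−p)` (Balding–Nichols — chosen precisely because its first two
  moments are analytic and testable). Optional admixture pulses mix
  tip frequencies linearly. Genotypes are Binomial(2, p) per diploid;
  the outgroup is homozygous ancestral and never missing (it exists to
  polarize); missingness is i.i.d. per ingroup genotype; positions are
  uniform without replacement, sorted, 1-based on output; REF/ALT
  orientation is randomized so polarization is actually exercised.
  The default `seal_model()` has one heavily drifted focal branch
  (F = 0.5), a mildly drifted shared branch (F = 0.02) and four weakly
  drifted terminal branches (F = 0.05).
* **Trajectories** are exact piecewise-constant `m(t)` tables;
  replicate pairs optionally perturb `m` by a lognormal factor
  (SD 0.05–0.1 is typical between-pair estimation noise). Truth
  crossing times are recorded twice — closed form and independent
  fine-grid integration — and must agree to 1e−6 relative.
* **Dentition presets** encode the qualitative focal pattern: short M1
  (low M1/P4), overlapping P4, tall anterior crowns, small top-cusp
  angles, zero probability of five-cusped teeth. A shared per-specimen
  size factor (SD 0.06) makes within-specimen ratios less noisy than
  single measures, which is what makes the M1/P4 ratio the best
  classifier — the same mechanism as in real material. Nominal means
  are in the 6–8 mm range typical of ringed seal postcanines; they are
  *not* measurements.
* **Crown/tongue outlines** are closed-form polylines (adjoined
  isoceles triangles; power-law half-width profiles) whose metrics
  have analytic truths.

What a green test therefore establishes: that the *implementations* of
the statistics are correct against independent oracles, and that the
pipeline recovers planted qualitative structure. It does not establish
that real data would show the same magnitudes — the generators have no
mutation process, no linkage, no coalescent genealogy, and no
measurement protocol for teeth.

## A known, deliberate red test

One acceptance property asserts that the focal population shows the
strictly largest private-pattern proportion at *every* subsample size
n = 1..5 under the default generator. A frequency-level Monte Carlo of
the generator's own model shows this is false: presence
(≥ 1 derived copy among 2n chromosomes) is a concave function of
allele frequency, so pure drift *lowers* the focal population's own
presence probability and simultaneously raises its absence
probability, which boosts the other populations' private patterns at
small n. The focal population wins only at n ≥ 4, where the
derived-count filter couples populations: a pattern private to a
weakly drifted population then requires that population alone to carry
several derived copies, which weak drift rarely produces. In real
data the focal population wins at all n because of new mutations on
its long branch and because migration homogenizes the non-focal
populations — mechanisms a per-branch frequency-drift stand-in cannot
produce. The assertion is kept as stated and left failing rather than
tuning generator parameters toward it; the companion assertions
(PC1 separation, AUC ordering, deep/shallow split-time contrast) pass.

## Numerical notes

* Beta parameters degenerate as F → 0; `F = 0` short-circuits to the
  parent frequency.
* NJ distance matrices that are identically zero return an explicit
  star tree rather than an arbitrary resolution.
* The grid integrator subdivides segment pieces to ≤ 1 generation; for
  piecewise-constant rates the midpoint rule is then exact up to
  floating accumulation, which is why 1e−6 relative agreement is a
  fair requirement rather than an optimistic one.
* Exact permutation enumeration switches to Monte Carlo above 20,000
  arrangements; both branches count ties as extreme.
* All randomized operations take explicit integer seeds and are
  byte-reproducible; file writers emit deterministic text.

## Limitations

* The NJ stand-in underestimates what ML inference with proper
  ascertainment correction would recover; monophyly fractions from it
  should be read qualitatively.
* Only biallelic SNPs are handled; multi-allelic records are dropped
  at VCF read with a logged reason.
* IM trajectory *fitting* is out of scope — the package consumes
  fitted rate tables.
* Tongue landmarks (tip, posterior body end) must be supplied; no
  image processing is attempted.
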