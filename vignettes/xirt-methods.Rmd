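---
title: "Models and methods behind xirt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind xirt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xirt)
library(dplyr)
```

xirt analyzes DNA replication timing (RT) and chromosome conformation in
the context of X-chromosome inactivation (XCI): how the inactive X (Xi)
switches to rapid, near-uniform late replication as it forms, how loss of
the maintenance factor SmcHD1 reverses that switch in a subset of domains
(SmcHD1-dependent, "SD", domains), and how those domains sit at the Xi
surface, contact each other and other chromosomes, and coincide with XCI
escapees. This vignette documents the models each stage implements, the
parameters that matter, the numerical choices, and what the bundled
synthetic-data generator does and does not emulate.

## Bulk RT profiles

Population Repli-seq sorts BrdU-labeled cells into early-S and late-S
fractions and sequences the immunoprecipitated nascent DNA of each. After
counting reads in bins (sliding windows -- 200 kb at 80-kb steps -- for
non-haplotype analysis; non-overlapping 400-kb bins for haplotype-resolved
profiles), `rt_score()`:

1. scales each fraction to reads per million (RPM), removing library-depth
   differences;
2. forms the early ratio $r = E/(E+L)$ per bin on the scaled counts;
3. maps it to the RT score $\mathrm{rt} = 2r - 1 \in [-1, +1]$, positive =
   early, negative = late, zero at equal coverage;
4. sets bins whose scaled total $E+L$ falls strictly below the 5% quantile
   (or is zero) to missing -- explicitly `NA`, never 0, because an RT of 0
   is a meaningful "mid-S" value.

The affine map in step 3 was an open design point: the score only needs to
be a monotone function of $r$ confined to $\pm 1$. We use $2r-1$ because it
is the unique affine choice with those endpoints and a fixed point at
$E = L$; a rank-based rescaling would destroy the ratio interpretation and
make scores depend on the genome-wide score distribution.

`normalize_profiles()` quantile-normalizes profiles to the mean of the
per-sample sorted value distributions (the usual reference), excluding
missing bins from the rank mapping and preserving them as missing; tied
values share the average reference value. Replicate averaging, when
requested, happens after quantile normalization, so that each replicate
contributes on a common scale before the elementwise mean; with the order
reversed, a replicate with a compressed dynamic range would drag the mean
toward mid-S before normalization could correct it.

The bottom-5% filter is computed per early/late sample pair on the
RPM-scaled totals, before normalization and pooling. Ties at the quantile
are kept (only strictly-below totals are removed), so the filter never
removes more than the requested fraction because of discrete counts.

## RT classes

Two classifications operate on replicate-mean, quantile-normalized 400-kb
profiles.

**Differentiation classes** compare the stem-cell (ESC) and differentiated
(NSC) states: EtoE (both RT > 0), LtoL (both < 0), EtoL (positive to
negative with a difference > 0.5) and LtoE (the reverse). A sign change
below the 0.5 threshold is `unclassified`; a missing input is `filtered`.
All threshold comparisons are strict, so an exact-zero RT is
`unclassified` rather than silently early or late.

**SmcHD1 classes** add the mutant NSC profile. A bin is *affected* when
the mutant replicates it earlier by more than 0.4 RT units
($\mathrm{rt}_{KO} - \mathrm{rt}_{WT} > 0.4$). The test is signed by
default -- the biology of interest is RT *reversal toward early* -- with an
`absolute` option for two-sided scanning. Classes: SD (EtoL and affected),
SI (EtoL, not affected), CL (LtoL, not affected), CE (EtoE, not affected).
Affected bins outside EtoL get an explicit `affected_other` label rather
than being merged anywhere; they are rare but real (mostly LtoL bins that
reverse), and hiding them would bias span bookkeeping. `class_spans()`
reports bins and Mb per class as exact arithmetic on the fixed bin width.

Bins are classified independently; we deliberately do not smooth or merge
bins into multi-bin domains before labeling, so a class track is exactly
reproducible from the profiles.

## Single-cell Repli-seq

A single S-phase cell has replicated some fraction of its genome;
replicated bins carry twice the copy number of unreplicated ones.
`binarize_cell()` recovers that binary state from binned counts:

1. per-bin ratio of library-size-scaled cell counts to a G1 reference
   (copy-number control), with a 0.5 pseudocount on both counts, log2
   transformed. Bins without G1 coverage are missing;
2. a two-state Gaussian hidden Markov model along each chromosome with
   fixed sticky transitions (self-transition 0.99) and emission means and
   variances re-estimated by EM; posterior decoding. EM runs from three
   deterministic initializations (symmetric quartiles; median and
   median + 1; median − 1 and median) and keeps the best likelihood, which
   matters for cells near the start or end of S where one state dominates;
3. the state with the higher mean log-ratio is replicated. A genuine
   unreplicated/replicated split sits ~1 log2 unit apart, so if the fitted
   means are closer than `min_sep = 0.6`, the "split" is noise rather than
   copy number and the FACS gate decides instead: the whole cell is
   assigned to the gate's majority state (unreplicated for the early-S
   gate, replicated for mid/late), mirroring how copy-number binarizers
   anchor the most frequent state to a somy level per gate. A collapsed EM
   fit falls back to a deterministic two-means threshold with a warning.

The sticky HMM assumes spatially coherent replication domains, which real
genomes have; on spatially random states it will over-smooth. That is a
feature, not a bug: isolated single-bin flips at this depth are far more
likely Poisson noise than real.

`percent_replication()` scores a cell's S-phase progression as the
percentage of non-missing bins replicated, with a mask to exclude the X --
otherwise the late-replicating Xi biases the genome score that the
kinetics fits use as their x-axis.

### Replication kinetics (T10--90%)

`fit_t1090()` models a chromosome's percentage replication $y$ against the
genome's $x$ across cells. Cells are ranked by $x$ and split into 18
equal-count groups (remainder cells join the earliest groups; ties keep
input order), group means are formed, and the pseudo points (0, 0) and
(100, 100) are appended to pin the ends of S, stabilizing the fit where
sorted cells are sparse. Two models:

* linear, $y = ax + b$, for Xa/autosome-like gradual replication;
* sigmoid, $y = 100/(1+e^{-k(x-x_0)})$, for Xi-like abrupt replication.
  The 2-parameter logistic with fixed 0/100 asymptotes is the simplest
  monotone model whose tails the pseudo points can pin; freeing the
  asymptotes adds nothing identifiable from 20 points.

T10--90% is the S-phase time from 10% to 90% fitted replication,
$(x_{90} - x_{10})/100 \times S$ with $S = 10$ h, clamped to $[0, S]$. On
the identity line the linear model gives exactly $0.8\,S = 8$ h -- the
autosomal benchmark -- and for the sigmoid the closed form is
$t_{10\text{--}90} = (2\ln 9/k)/100 \times S$. Sigmoid starting values come
from a logit linearization, then the slope at the 50% crossing, then fixed
fallbacks; the Levenberg-Marquardt fit reports all attempted starts if it
ever fails to converge.

### Single-cell RT values (scRT)

`per_bin_percent_replication()` gives each bin the percentage of scored
cells that have replicated it. `scrt_values()` ranks bins from highest to
lowest percentage, forms 100 equal-count percentile groups (tied
percentages share a group, so equal evidence always maps to equal time),
assigns each group its mean percentage $\bar p$, and converts to S-phase
time $t = S(1 - \bar p/100)$, rounded half-up to 0.1 h. Under uniform
sampling of cells across S, a bin replicating at time $t_b$ is replicated
in a fraction $(S - t_b)/S$ of cells, so this mapping is the unbiased
inverse; it is a non-increasing step function of $\bar p$ with range
$[0, S]$. Equal-count grouping (rather than equal-width) keeps group means
equally reliable when the percentage distribution is very uneven, as it is
on the Xi.

## Virtual 4C and interaction calling

`virtual_4c()` extracts a one-viewpoint profile from a binned, symmetric
contact matrix: the rows of all bins inside the 400-kb viewpoint (80 rows
at 5-kb resolution) are summed, the viewpoint span plus a 50-bin flank is
masked in cis (undigested/self-ligation artifacts dominate there), and the
remainder is scaled to 10,000 total -- making profiles comparable across
viewpoints and invariant to sequencing depth.

`far_cis_calls()` binarizes the cis profile (coverage = signal > 0) and
slides a 50-bin test window (step 1) against a 1,200-bin background window
centered on it, excluding the test window itself. With background covered
fraction $p$, a window covering $k$ of $n$ scored bins gets
$z = (k - np)/\sqrt{np(1-p)}$ and a one-sided upper-tail binomial p-value;
Benjamini-Hochberg across windows at FDR 0.01; adjacent or overlapping
significant windows merge into interaction intervals. The binomial test on
binarized coverage is the natural formalization of "relative enrichment of
binary coverage" and is exactly checkable against brute-force window
enumeration, which the test suite does. Windows whose background coverage
is exactly 0 or 1 have no defined enrichment and are excluded from FDR
control rather than given fake p-values. A centered background (not
trailing) keeps the test symmetric around each window; both the window
sizes and the FDR are exposed as arguments, and fragment-indexed signal
can be tested with the fragment-scale parameters (w = 100, W = 3000)
instead.

`trans_calls()` applies the same test to every other chromosome with
250-bin windows tiled at half-window steps -- a compromise between a
1-bin slide (50 times the multiplicity) and disjoint tiling (half-window
offsets can straddle a real block) -- using the viewpoint's genome-wide
trans covered fraction as background; BH runs across all trans windows and
the number of merged significant intervals is the viewpoint's trans
interaction count. For 4C fragment tracks, `smooth_fragments()` provides
the 201-fragment centered running mean (truncated at chromosome ends) and
`assign_allele()` the exact-match SNP demultiplexer (one mismatch =
unassigned). `rebin_z()` averages window z scores onto 400-kb bins for
comparison with RT tracks, and `aggregate_pairs()` averages contact
submatrices around all ordered pairs of a bin set (skipping pairs at the
matrix edge) to visualize focal same-class contacts; `center_corner_ratio()`
summarizes the enrichment.

## Enrichment

`bin_track_mean()` averages positional signal in non-overlapping bins
(empty bins missing, not zero); `log2_differential()` forms
$\log_2(KO/WT)$ per bin with non-positive inputs missing.
`xi_probability()` is the Xi read share $x_i/(x_i + x_a)$ of
allele-resolved expression: 0 = fully silenced, 0.5 = balanced biallelic
expression (full reactivation). `density_by_class()` assigns features to
the class of the bin containing their midpoint (genes spanning a boundary
must land somewhere; the midpoint is deterministic and unbiased), then
reports counts, spans, per-Mb densities, densities normalized by a second
feature set (escapees per gene density, removing gene-density confounding)
and fold changes versus a reference class, computed on normalized
densities when a normalizer is supplied and raw densities otherwise --
both raw and normalized columns are always reported.

## The synthetic-data generator

Every stage above can run against generated data with known truth:

* `make_genome()` tiles chromosomes with fixed-width bins (0-based
  half-open; terminal partial bins dropped).
* `graded_program()` gives each bin a mean replication time $t_b$ with
  logistic onset jitter (`noise_sd`, default 0.5 h): a cell at S-fraction
  $f$ has replicated bin $b$ with probability
  $\mathrm{logit}^{-1}((fS - t_b)/\sigma)$. States derive from one latent
  time per bin per cell, so replication is irreversible within a cell --
  independent per-$f$ Bernoulli draws would let a bin "unreplicate".
* `xi_program()` draws one onset per cell from a Normal(6.5--7, 0.75 h)
  truncated to the second half of S (the Xi initiates there), and
  replicates each X bin at onset + Uniform(0, `duration`): rapid,
  near-uniform late replication with cell-to-cell onset jitter. The
  truncated-Normal/Uniform split separates the two variance sources the
  single-cell data show: between-cell onset spread and within-cell
  duration. `xi_program_t1090()` computes the program's true population
  T10--90% from the latent-time CDF by numerical integration, and
  `xi_duration_for_t1090()` inverts it, so kinetics-recovery experiments
  can plant an exact truth.
* counts are Poisson with expectation `depth` × (1 + state), with a
  Gamma-mixing `overdispersion` knob (negative binomial) when Poisson is
  too clean.
* `simulate_bulk()` pools cells at the FACS midpoint ($f < 0.5$ early,
  $f \ge 0.5$ late; the real gates are unquantified, and the midpoint
  makes the two fractions symmetric) and draws Poisson counts around each
  fraction's mean replicated state.
* `simulate_contacts()` builds a symmetric Poisson contact matrix: cis
  decay $\propto d^{-1}$, per-layer trans rates for the layered (X)
  chromosome, contact-permissive autosomal blocks (10% of bins, 6-fold)
  that concentrate trans contacts the way real trans contacts concentrate
  at a minority of regions -- without them trans coverage is spatially
  flat and no window can be enriched over its own background -- and an
  optional same-layer cis pair boost to plant SD-SD hotspots.

Uniform sampling of cells across S is assumed throughout (the true
sampling density of sorted cells is unknown); the percentage-replication
x-axis makes the kinetics fits insensitive to mild deviations.

What the generator does **not** emulate: read-level artifacts (GC and
mappability bias, blacklisted regions), whole-genome-amplification noise
beyond overdispersion, haplotype phasing errors, Hi-C
distance-dependent ligation artifacts beyond the power-law, and
compartment checkerboards. Tests passing on synthetic data therefore
validate the *computations* -- scoring, segmentation, testing, bookkeeping
-- not robustness to platform artifacts.

## Problem sizes and tolerances

The test and acceptance experiments run at deliberately reduced scale,
chosen so every recovery property is comfortably identified: bulk recovery
uses 200 x 400-kb bins at depth 50--100 with 2,000--3,000 cells pooled;
single-cell pipeline recovery uses 400 x 100-kb bins, 200 cells, depth 50
(RMSE ≤ 0.5 h against the planted program); kinetics recovery uses
scaled-down chromosomes (two 100-Mb autosomes, one 160-Mb X) with 100
cells and 20 replicate seeds, asserting the seed-averaged fitted T10--90%
within ±0.5 h of the planted 3.0 h -- individual seeds scatter with
sd ≈ 0.45 h, which is genuine cell-to-cell Xi onset heterogeneity, not
estimator error; interaction calling is checked for exact equality with
brute-force enumeration on 2,000-bin profiles over 50 seeds and for null
false-call control (≤ FDR + 0.01 over 200 homogeneous-coverage
replicates).

## Known limitations

* The binarizer's gate-majority rule mislabels a cell whose true
  replicated fraction contradicts its FACS gate *and* whose two states are
  not separable; such cells are rare but possible near gate boundaries.
* The sigmoid T10--90% is undefined for non-increasing fits; the fit
  errors rather than returning a clamped value.
* `aggregate_pairs()` does not correct for distance-dependent expected
  contacts; near-diagonal pairs inherit the 1/d convexity (the
  random-pair baseline on a decaying matrix sits slightly below 1).
  Comparisons should use a matched random bin set, as the tests do.
* Quantile normalization across samples with very different missingness
  interpolates the reference distribution; the identical-multiset
  guarantee is exact only for equal non-missing counts.
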