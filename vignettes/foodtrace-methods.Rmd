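---
title: "Methods: from dietary extract to plasma to microbiome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from dietary extract to plasma to microbiome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`foodtrace` implements a complete analysis chain for a common gnotobiotic
study design: mice are colonized with human donor microbiomes (HU) or kept
on a low-complexity community (LCM), gavaged with a dietary extract such as
green tea, and the question is which extract-derived compounds reach plasma
and how their abundances relate to gut microbiome composition and
diversity.  This vignette describes each stage's model, its assumptions,
the tunable parameters, the numerical choices, and what the synthetic study
worlds used for validation do and do not emulate.

## Compound tracking

The tracking stage mirrors a targeted data-extraction workflow on
vendor-exported feature lists (not raw spectra; spectral deconvolution and
database annotation are upstream concerns).  A compound is *defined* by the
extract: it must be present in 100% of extract replicates (mass within a
10 ppm window of the replicate consensus, retention time within ±0.2 min),
elute before 10 min, and be absent from preparatory blanks.  Consensus mass
and retention time are arithmetic means over replicates — a stable choice
for the typical 4 replicates.

Matching into plasma uses the same windows plus a 0.3 min *outlier* cut
against the extract consensus.  Qualification uses the isotope ratio: when
a plasma feature carries an M2 (first ¹³C isotopologue) peak, its M2/M1
ratio must sit within 20% relative deviation of the extract's own observed
ratio; a feature with no M2 peak is quantified on M1 alone and is not
disqualified.  We use the extract's observed ratio rather than a
theoretical isotope envelope because the extract replicates are measured on
the same instrument and the observed ratio absorbs detector nonlinearity.
A secondary adduct mass, when present on both sides, is checked for
equality within the ppm window but never quantified.  When several plasma
features fall inside both windows, the match resolves to the smallest ppm
deviation, then the smallest retention-time deviation, then the
lexicographically smallest feature id — a deterministic rule, since vendor
software does not document its own.

Detection requires presence in at least 3 plasma samples with area
≥ 20,000 counts (aqueous fraction) or ≥ 55,000 counts (lipid fraction);
boundaries are inclusive, and sub-threshold areas of surviving compounds
are preserved.  Finally, any compound matched in plasma of animals never
given the extract is a *baseline* compound and is removed; the
`tracking_report` enforces the conservation identity
`retained = detected − baseline-removed` per fraction and in total.

Plasma feature lists are truncated at load time to the retention-time range
with acceptable signal-to-noise: 10.4 min (lipid) and 13 min (aqueous).
All of these are fields of `match_params()` and configurable.

## Diversity

Rarefaction subsamples each sample without replacement to a fixed depth
(default 40,625 reads — chosen as the kind of value a study would pick as
the largest depth that excludes no sample; the generator draws depths
uniformly above it).  Samples are processed in table row order under one
seed, so a run is exactly reproducible.

Faith's phylogenetic diversity and unweighted UniFrac share one spanning
convention, stated explicitly because implementations differ: a branch is
spanned by a community if and only if its subtree contains at least one
present tip, so the stem from the root down to the community's most recent
common ancestor **is** included.  PD is the summed length of spanned
branches; UniFrac is the length spanned by exactly one of two communities
divided by the length spanned by their union.  Both are computed from an
edge-by-tip incidence matrix built in one postorder pass, and both are
verified in the test suite against a brute-force oracle that enumerates
tip-to-root paths edge by edge (agreement to 1e-10 over dozens of random
trees).

UniFrac is computed on the rarefied table; Bray-Curtis on raw compound
areas.  Rarefying presence/absence data before UniFrac removes the
depth-driven component of richness differences; compound areas are already
on a common instrument scale so no resampling is applied there.

## Centroid collapsing

Replicate mice colonized from one donor are pseudoreplicates for any
question about donor microbiomes, and permutation tests have no random-
effect machinery to absorb that.  Distances are therefore collapsed to one
centroid per *treatment unit* (donor for HU mice, experimental cohort for
LCM mice; 29 mice become 13 units) using the distance-only identity

d²(C_A, C_B) = mean_{a,b} d²(a,b) − ½ mean_{a,a′} d²(a,a′)
             − ½ mean_{b,b′} d²(b,b′),

which equals the Euclidean distance between coordinate centroids whenever
the input is Euclidean-embeddable (tested against that oracle to 1e-8).
Unweighted UniFrac is not always embeddable, so the identity can go
slightly negative; such squared distances are clipped to 0 with a warning.
Non-distance data (compound abundances, PD) are collapsed by arithmetic
means over the same units.

## Ordination and the Procrustes test

PCoA is the eigendecomposition of the Gower-centered matrix −½ J D² J.
Axes with positive eigenvalues (relative tolerance 1e-9) are kept and
scaled by the square root of the eigenvalue; negative-eigenvalue mass is
reported, and proportions explained are taken relative to the total
absolute eigenvalue mass so they can never exceed 1.

Procrustes superimposition centers both configurations, scales each to unit
sum of squares, zero-pads to a common axis count (all retained axes are
used — no arbitrary axis cut), and minimizes the residual over orthogonal
transformations (reflections allowed) and a least-squares scale.  The
minimized residual is Gower's statistic m² = 1 − (Σσ)² ∈ [0, 1], where σ
are the singular values of X′Y.  The randomization test permutes the row
order of the target configuration; p = (#{m²_perm ≤ m²_obs} + 1)/(B + 1).
The +1 correction avoids p = 0 and differs from a raw proportion by at most
1e-4 at B = 10⁴; "≤" (better-or-equal fits count against the null) is the
conservative reading.  Calibration is checked directly: over 200 null
replicates the rejection rate at α = 0.05 stays inside the binomial 95%
band.

## PERMANOVA

The McArdle–Anderson partition operates on G = −½ J D² J: with H the hat
matrix of intercept + predictor,
pseudo-F = [tr(HGH)/q] / [tr((I−H)G(I−H))/(n−q−1)] and R² = tr(HGH)/tr(G).
A continuous predictor is centered and uses q = 1, giving the marginal
single-covariate test; categorical predictors are dummy-coded.  The
permutation scheme is unrestricted row permutation of the predictor —
valid here precisely because the test runs on collapsed treatment-unit
centroids.  The permutation loop evaluates tr(H G[π,π]) directly, which
makes 10⁴ permutations cheap at n = 13.  The implementation is checked
against `vegan::adonis2` (identical F and R²) and against exhaustive
enumeration of all 720 permutations at n = 6.

The per-compound composition screen runs one continuous-predictor PERMANOVA
per compound on the centroid tables, BH-adjusts across compounds, and flags
raw-p and FDR significance separately (studies of this size typically
report both).  Per-compound failures (e.g. a constant abundance) become
flagged rows, never aborts.

## Regression screens

**Diversity screen.** Each compound's z-scored abundance is regressed on
Faith PD.  The direction — compound as response, PD as predictor — makes
the slope "SD of compound per PD unit", comparable across compounds.
Regressions where any observation has |DFFITS| > 1 are excluded outright
(DFFITS is the studentized change in fit upon deleting the point; the
implementation is verified against leave-one-out refits to 1e-10, and a
perfect fit is defined to have DFFITS 0).  Surviving regressions use CR1
cluster-robust standard errors — the sandwich variance with score blocks
summed within treatment units, small-sample factor G/(G−1)·(n−1)/(n−k),
and a t reference with G−1 degrees of freedom — then BH adjustment.

**Taxon screen.** Every (compound, taxon) pair is fit as

z(compound) ~ β · arcsinh(100 · relative abundance) + (1 | treatment unit) + ε

by REML, with Wald-t inference on β using Satterthwaite degrees of freedom
(falling back, flagged, to G−1 on numerical failure).  The arcsinh
transform is variance-stabilizing and maps zero abundance to exactly zero.
When the intercept variance estimates to zero the fit coincides with OLS.
Influence is handled by exact leave-one-observation-out refits: a pair is
excluded when max_i |β̂ − β̂₍₋ᵢ₎| / se(β̂) ≥ 4.  Refitting is exact and
affordable at this scale (tens of observations), which we prefer over
closed-form mixed-model deletion approximations.  The screen runs across
all mice and, separately, HU-only — the LCM community's radically different
architecture can dominate pairwise signals and strain the random-effect
assumption.  Simulation shows the slope estimator has < 5% bias and 93%
CI coverage under the study's 10 × 2 design.

## Balance selection

For compounds associated with composition, a two-taxon (extendable)
log-ratio balance is sought:
B = √(pq/(p+q)) · [mean ln x over numerator − mean ln x over denominator].
The search scores every unordered taxon pair by the R² of a linear
regression of the response on the balance (R² is invariant to orientation;
the numerator is then oriented so the slope is non-negative, with ties
broken lexicographically), then forward-adds the single taxon that most
improves R² to either side until `max_size` or no improvement.  Zeros are
handled by a pseudocount of half the smallest nonzero relative abundance.
Cross-validated R² refits the regression coefficients per fold on the
*selected* balance (selection itself is done once on the full data; at
n = 13 treatment units, per-fold re-selection would be dominated by
selection noise, and the spirit of "10-fold CV at n = 13" degrades
gracefully toward leave-one-out).  The candidates fed to the search are the
compounds ranked top by raw PERMANOVA p in the composition screen.

## The synthetic study worlds

The generator produces everything the pipeline consumes — phylogeny, mouse
microbiomes, metadata, plasma compound tables, LC-MS feature lists — plus a
ground-truth ledger, deterministically per seed.

* **Phylogeny**: random bifurcating topology, exponential branch lengths.
* **Microbiomes**: each of 10 donors gets a sparse Dirichlet base
  composition over a random 45-ASV support (a 12-ASV core is shared by all
  donors and hosts the planted effects); each of 2 replicate mice resamples
  the donor base (Dirichlet, concentration `mouse_tau = 8`) and is observed
  multinomially at a depth drawn uniformly in [40,625, 80,000], so the
  default rarefaction depth never excludes a sample.  These concentrations
  were calibrated once so replicate pairs sit near unweighted UniFrac 0.25
  and different donors near 0.5, and then frozen.  Nine LCM mice in three
  cohorts draw from a base in which 6 ASVs carry 99% of the mass; in the
  observed counts the dominant block stays above 90–97% and LCM Faith PD
  sits clearly below HU.
* **Compounds**: planted constructs are built on a standardized scale —
  linear in the standardized arcsinh-percent abundance of a prevalent host
  ASV (slope 1), in standardized Faith PD (slope −1), or in a planted
  two-taxon log ratio — with Gaussian noise (sd 0.3), standardized, and
  mapped affinely to positive peak areas, so the screens' z-scoring
  recovers the construct exactly.  The ledger records both the injected
  slope and the realized *effective* slope on each screen's scale (slope of
  the standardized construct on the raw predictor), which is what an
  unbiased screen should estimate.  Remaining compounds are lognormal
  noise; a subset of those are marked baseline-present.
* **LC-MS features**: extract replicates carry ≤ 2 ppm / 0.02 min jitter;
  true plasma features are displaced ≤ 5 ppm and ≤ 0.1 min with consistent
  isotope ratios; decoys are displaced > 15 ppm or > 0.5 min; blank
  contaminants appear in every extract replicate and the blanks; baseline
  compounds also appear in unexposed-animal plasma.  At default
  `match_params()` the tracking stage provably recovers exactly the
  non-baseline true compounds.

What the worlds do **not** emulate: taxonomy (ASV labels are opaque, so
"genus-level" collapsing is stood in for by the ASV table), realistic
isotope envelopes, chimeric reads or contamination of the sequencing data,
compositional count noise in the compound tables, and any correlation
between a compound's LC-MS behavior and its biology.  Passing tests
therefore demonstrate the correctness and calibration of the statistical
machinery under the declared generative model, not performance on real
instruments.

## Problem sizes and runtime

Default analyses run on the study-scale design (29 mice, 13 treatment
units, 120 ASVs, 60 plasma compounds, 10⁴ permutations where a single test
is run).  Test-suite and demonstration runs use 999 permutations, an
8 × 8 compound-by-taxon mixed-model grid (the most variable retained
compounds by coefficient of variation against the most prevalent, most
variable taxa — exact leave-one-out influence makes each pair cost n + 1
REML fits), 200 null replicates for calibration checks, and 500 replicates
for mixed-model parameter recovery.  These sizes keep a complete validation
run in minutes on one core while leaving every statistical claim testable.

## Known limitations

* Unweighted UniFrac ignores abundance beyond presence; planted effects on
  abundant-but-ubiquitous taxa are invisible to the composition screen.
* The centroid-collapsing identity clips slightly negative squared
  distances to zero rather than projecting to the nearest Euclidean
  configuration.
* The greedy balance search is not exhaustive beyond pairs; a planted
  three-taxon balance may be found as a good two-taxon approximation.
* Influence-based exclusion (DFFITS > 1, leave-one-out ≥ 4) removes whole
  regressions; no robust-regression alternative is offered.
* The p-value convention (+1 correction, "≤" counting) is deliberately
  conservative; exact raw proportions differ by at most 1/(B + 1).
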