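---
title: "Glucosinolate pathway genetics, haplotype inference and field fitness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glucosinolate pathway genetics, haplotype inference and field fitness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucotype)
```

## The system

Aliphatic glucosinolates (GSLs) are methionine-derived defence metabolites
of *Arabidopsis thaliana*. Natural presence/absence polymorphism at a small
set of genes explains most of the leaf GSL diversity seen among accessions:
the transcription factors MYB28 and MYB29 set the overall aliphatic pool;
the MAM1/Elong locus sets the dominant side-chain length (4C when
functional, 3C when not); and the modification enzymes GSOX1/GSOX3 (MT to
MSO oxygenation), AOP2 (MSO to alkenyl), AOP3 (3MSO to OH-propyl, never on
4MSO) and GSOH (But-3-enyl to OH-But-3-enyl) reshape the side chain. AOP2
and AOP3 are alternate alleles at one locus; the Col-0 reference is null at
both. Because GSOH acts on a product of AOP2, AOP2 is epistatic to GSOH:
the GSOH state is chemically invisible unless AOP2 (and a 4C-dominant MAM1
background) supplies its substrate. ESP acts downstream of tissue damage,
on activation products, and never changes the intact-leaf profile.

The package connects this pathway to three analyses: (i) a forward model
from a multi-locus genotype to a predicted leaf profile, and the inverse
caller from a profile back to a seven-locus haplotype; (ii) a
linkage-equilibrium test asking whether multi-locus haplotype frequencies
in an accession panel are the product of their single-locus frequencies;
and (iii) the field-trial machinery — fitness computations, a split-plot
mixed model with Type II sums of squares, LSMeans with Dunnett/Tukey
comparisons, and PCA-based concordance of chemotypes across environments —
exercised end to end on synthetic data with known truth.

## The forward model and its calibration

`predict_profile()` is deliberately a rule model, not a kinetic one. Class
pools (3C-short, 4C-short, long) are scaled by the MYB states, split
between chain lengths by MAM1, and redistributed within a chain class by
the modification enzymes; conversions never change class totals, so total
aliphatic GSL depends only on the regulators.

The quantitative anchors are the relative totals that define the amount
classes used for haplotype calling: loss of MYB28 halves the total
aliphatic pool and abolishes the long-chain fraction, loss of MYB29 leaves
75% with the long chain intact, and the double knockout accumulates none.
With the default Col-0 pools of 3, 17 and 4 pmol/mm^2 (3C, 4C, long; a
long-chain fraction of 1/6), those totals pin the short-chain retention
multipliers at 0.6 (myb28) and 0.7 (myb29). Class-level percentage
statements in the source literature are mutually inconsistent with these
totals, so the totals — which define the chemotype classes everything
downstream uses — are the binding calibration; the class-level figures are
treated as qualitative.

Other defaults worth knowing:

* `aop_conversion = 1`: AOP2 converts the dominant-class MSO completely
  (observed profiles of AOP2 lines carry essentially no 4MSO). The minor
  chain class is left untouched.
* `gsoh_conversion = 0.5`: AOP2 lines with functional GSOH show But-3-enyl
  and OH-But-3-enyl side by side, so hydroxylation is modelled as partial.
* The dominant:minor short-chain split (85:15) and the distribution of the
  long pool over 5MSO–8MSO (0.10/0.05/0.10/0.75) are free parameters; the
  data only order them, never quantify them.
* `field_mode = TRUE` by default: field-grown material accumulates no MT
  GSL regardless of GSOX state (redundant paralogues), so MT — the only
  diagnostic for GSOX — appears only in chamber mode, where an impaired
  GSOX locus leaves `gsox_conversion = 0.3` of the short-chain pool
  unoxidized.
* ESP is carried through every genotype and never alters a profile.

`trace_concordance()` compares the predicted qualitative chemotype of each
of the 17 laboratory genotypes with the structure set visible in a single
representative field trace of that genotype. Nine genotypes match exactly.
The eight differences are all single-trace detection effects the
deterministic rules do not try to model: minor long-chain homologs
(5/6/7MSO) dropping below detection, 8MSO showing residually in myb28
backgrounds, and trace alkenyl or residual precursor in lines where the
model treats a conversion as complete. The test suite freezes these
difference sets rather than pretending they are absent.

## Haplotype calling and epistatic unobservability

`call_haplotype()` inverts the rules with explicit numeric thresholds
(`caller_thresholds()`), because the source material describes the calls
qualitatively:

* `detection_limit = 0.5` pmol/mm^2 — presence threshold per structure;
* `dominance_ratio = 2` — minimum major:minor chain-class ratio before
  MAM1 is called rather than left `NA`;
* `amount_breaks = c(0.05, 0.625, 0.875)` — midpoints between the
  calibrated 0/50/75/100% total-aliphatic classes, relative to a
  Col-0-equivalent `reference_total`. When no reference is supplied,
  panel-level calling uses the panel's upper-quartile total, a robust
  stand-in given that absolute totals vary across environments.

MYB28 is called from long-chain presence first and the amount class
second; combinations matching no expected pattern leave MYB29 `NA` with a
warning rather than guessing. Epistasis produces structural `NA`s: with no
aliphatic GSL at all, MAM1, GSOX, AOP and GSOH are unobservable; GSOH is
unobservable without AOP2 and a 4C background; GSOX is unobservable in
field material; ESP is always unobservable. `round_trip()` checks a
genotype through `predict_profile()` and back, requiring the correct call
at every observable locus and `NA` exactly at the unobservable ones — all
17 laboratory genotypes pass noise-free, and under multiplicative
lognormal noise with CV 0.2 the expected locus agreement stays above 95%
(the amount-class boundaries are the only fragile calls; each affects one
locus of seven).

## The linkage-equilibrium frequency test

`expected_haplotype_frequencies()` builds the product-of-marginals
expectation over the observable state space. Structural `NA`s are
marginalized: the both-MYB-off state aggregates all downstream states, and
GSOH contributes a factor only where it is observable. The resulting space
for the six variable loci has 49 states and its probabilities sum to one
by construction.

`observed_vs_expected_test()` computes the Pearson chi-square over all
states with positive expectation. Two references are available:

* **Asymptotic**, with `df = states − 1 − estimated frequencies`. With a
  panel of ~144 accessions spread over 49 cells, many expectations fall
  below 1 and the asymptotic reference is unreliable; it is retained for
  comparison.
* **Monte-Carlo** (default, 10,000 replicates, mandatory seed). Because
  the expectation is estimated from the same panel, the resampler
  re-estimates the allele frequencies inside every replicate (`refit =
  TRUE`) — a parametric bootstrap. Conditioning on the fitted expectation
  without re-estimation (`refit = FALSE`) is markedly conservative
  (empirical size near 0.02 at nominal 0.05); the refitted version holds
  the nominal level within Monte-Carlo error.

Per-haplotype deviations use two-sided exact binomial tests of each cell,
reported raw (used for the over/under classification, as in descriptive
haplotype maps) and Bonferroni-adjusted. Profiles whose call carries a
non-structural `NA` (an ambiguous amount class) have no place in the state
space; `haplotype_frequency_test()` drops them with a warning and reports
the count, rather than letting a calling failure masquerade as an infinite
chi-square contribution.

Two calibration caveats are worth separating. The level statement above
concerns the test given correct calls (verified by simulating panels
directly on the state space). Run end to end on noisy profiles, the
pipeline can exceed its nominal level even without true linkage: caller
errors concentrate near the amount-class boundaries and are therefore
correlated with the underlying haplotype, which manufactures a little
apparent LD. At profile noise CV 0.15 the effect is visible but mild;
interpreting borderline global p values from heavily noisy panels should
keep it in mind. A practical note on power: a
single haplotype enriched twofold at n = 144 moves the global statistic
very little once the marginals re-adapt (the signal spreads over ~35–48
df), so the global test has low power against that alternative; the
per-cell binomial flags carry the power (the enriched cell is flagged
"over" in ~90% of such panels). The global statistic earns its keep
against diffuse, many-cell departures.

## Fitness and normalization

Absolute fitness is total fruit count × mean silique length × survival,
with two conventions: including survivorship (non-survivors score exactly
zero) or excluding it (defined only for survivors). Relative fitness
divides genotype means either by the unweighted mean of genotype means in
the environment (default; relative fitness then averages exactly one per
environment) or by the Col-0 reference mean (Col-0 is then one
everywhere). Both appear in the source analyses; the population-mean
convention is the default because it is the one under which environments
are directly comparable. "Population mean" is taken as the mean over
genotype means, not over plants; in the balanced design the two
essentially coincide. `mean_normalize()` rescales genotype-by-environment
means so each environment averages to the grand mean; it is idempotent.

## The split-plot model

The field layout is a split plot: whole plots (rows of ten blocks) receive
a pesticide treatment, blocks nest in plots, and every block contains each
genotype once. The default sizes are 17 genotypes × 3 environments × 2
treatments × 2 plots × 10 blocks = 2,040 plants, 120 blocks, 12 plots.

`fit_split_plot()` fits `trait ~ G*E*T` with a random plot intercept. The
single variance ratio is profiled by REML in one dimension via exact
whitening of the plot-block covariance; for balanced complete data the
closed-form stratum estimator is used (it coincides with REML there,
verified against lme4 to about seven digits, including at the zero
boundary). Type II sums of squares come from full-versus-reduced
generalized-least-squares comparisons respecting marginality. Two
denominator conventions are provided because the source table layout does
not say which was used:

* `containment` (default): classical split-plot strata — environment,
  treatment and their interaction tested against the among-plot mean
  square (12 − 6 = 6 df by default), all genotype-involving terms against
  the subplot residual. On balanced data this reproduces
  `aov(y ~ G*E*T + Error(plot))` exactly.
* `residual`: whitened-GLS sums of squares tested against the REML
  residual variance. With the plot variance fixed at zero this collapses
  to ordinary Type II ANOVA exactly.

The plot component is tested by a REML likelihood ratio against the
plot-free model on the ½χ²₀ + ½χ²₁ mixture. One limitation is inherent to
the design, not the estimator: with 12 plots there are only 6 df of
whole-plot error, so any plot-variance estimate carries χ²₆-type sampling
noise — about ±35% typical relative error per dataset. Across replicates
the median estimate recovers simulated plot-to-residual ratios of 0.1–1.0
within 11–19%, but no estimator can make a single 12-plot trial pin the
plot variance tightly.

`lsmeans()` averages model predictions over the other factors with equal
weights (equal to raw means on balanced data). `dunnett_vs_control()`
adjusts family-wise by simulating the maximum absolute standardized
contrast from the fitted covariance (10^5 draws by default; a Bonferroni
fallback is provided); `tukey_all_pairs()` uses the studentized range and
emits the usual compact letter display. Ordinal leaf damage (0–10) is
analysed as numeric, matching the source model formula, and survival is
modelled with the same linear model — a documented simplification, not an
endorsement; rows with missing traits are dropped, never imputed.

## PCA concordance across environments

`fit_pca()` performs covariance PCA (concentrations share units) of the
genotype-by-structure matrix of a reference environment, with component
signs fixed by making each loading's largest element positive so results
are bit-stable. Four components are retained by default: on the
calibrated noise-free means of the 17 genotypes they capture over 99% of
the variance (the chemotype space is spanned by the total-amount axis,
the 3C/4C flip, the alkenyl conversion and the hydroxylation split); a
three-component view is available via `n_components`. `project_scores()`
centers new genotype means by their own column means by default, so
environment-level shifts in overall GSL accumulation do not leak into the
scores; per-component Pearson correlations of reference versus projected
scores (`score_correlations()`) then measure whether genotype contrasts
are preserved — the reference correlates with itself at exactly 1.00 on
every component.

## What the generator does and does not emulate

`generate_trial()` reproduces the design invariants exactly (every block
contains every genotype once; plots nest strictly in
environment-by-treatment) and draws: lognormal fruit counts with additive
genotype, environment, treatment, G×E, plot and residual effects on the
log scale (fitness is non-negative and right-skewed); normal silique
lengths and flowering times; Bernoulli survival with G×E logit offsets;
leaf damage from a latent normal binned to 0–10; and per-plant GSL
profiles equal to the forward-model mean scaled per environment with
multiplicative lognormal noise. Default effect sizes (e.g. leaf damage:
genotype SD 0.5, environment SD 1, treatment SD 0.7, G×E SD 0.5, plot SD
0.3, residual SD 1.5 on the latent scale; survival base rate 0.85) are
assumptions chosen to produce the qualitative pattern of real trials —
strong genotype and G×E signal, weak treatment main effects — not
estimates of any particular dataset. `generate_accession_panel()` samples
haplotypes from the linkage-equilibrium product of configurable allele
frequencies (optionally enriching chosen haplotypes), expands hidden locus
states from their marginals, and emits noisy chamber profiles plus the
truth table.

What is *not* emulated: spatial autocorrelation within plots, herbivore
dynamics, measurement error structure of HPLC quantification beyond
lognormal noise, missing-data mechanisms other than mortality, and
population structure or geography in accession panels. Passing tests
therefore demonstrate that the estimators recover what the generative
model puts in — not that real field data satisfy these assumptions.

## Numerical choices and problem sizes

Deterministic checks (calibration ratios, round trips, df counts, oracle
equivalences against `aov`, `car::Anova`, `lme4` and exhaustive
enumeration) run at the full 17-genotype design. Simulation checks choose
sizes that keep the suite fast while leaving clear margins: null
calibration of the fixed-effect F tests uses a 6-genotype, 4-block
balanced layout (the tests are exact by construction, so size only affects
runtime); REML recovery and G×E power use the full 2,040-plant design;
frequency-test calibration uses 1,000 panels of 144 accessions with
299-replicate refitted Monte-Carlo; caller robustness uses 500 noisy
chamber profiles at CV 0.2. All simulations are seeded; identical seeds
give byte-identical synthetic data.
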