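---
title: "Statistical methods for small diet-group cohort studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for small diet-group cohort studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietmetab)
```

## The analysis problem

Cohort studies that compare omnivore, vegetarian, and vegan children are
necessarily small and unbalanced — a typical design has on the order of
24 omnivores, 10 vegetarians, and 6 vegans, aged roughly 1.4 to 7 years.
Group comparisons of biomarkers, dietary intakes, and anthropometrics in
such a design face three problems at once: tiny group sizes rule out
asymptotic tests, age and sex are potential confounders (diet groups are
not age-matched), and dozens of outcomes are tested together. On top of
the targeted panels sits an untargeted flow-injection TOF-MS metabolome
of several hundred ions, which needs its own machinery: putative
annotation, fold-change summaries, set-level enrichment, and
participant-level clustering.

`dietmetab` implements this analysis chain end to end, together with a
synthetic-cohort generator that reproduces the statistical structure the
chain assumes, so that every stage can be exercised and validated
without access to participant-level data.

## The probability index and the permutation test

The core two-group statistic is the probabilistic index

$$\mathrm{PI} = P(X > Y) + \tfrac12 P(X = Y),$$

estimated by exact pairwise comparison of the two samples. It equals the
Mann–Whitney $U/(n_1 n_2)$ under the midrank tie convention; 0.5 means
stochastic equality, and the two-sided test statistic is the distance
$|\mathrm{PI} - 0.5|$. Inference is by permutation of the group labels:
exhaustive enumeration of all $\binom{n}{n_1}$ splits when that is
feasible (up to $2\times10^5$ splits), otherwise Monte-Carlo shuffles
with the add-one correction $p = (\#\{T^* \ge T\} + 1)/(B + 1)$, which
never returns zero. Ties in the null are counted with $\ge$, the
conservative direction. The default $B = 47{,}500$ gives a p-value
resolution of about $2\times10^{-5}$, ample for panels of tens of
outcomes; it is overridable everywhere.

### Covariate adjustment

Age and sex adjustment uses a null-model residualization: the outcome is
regressed on intercept, age, and sex — never on group — and the test is
run on the residuals. The default permutation scheme is Freedman–Lane:
each null draw permutes the residual vector, re-residualizes it on the
same null model, and scores the result against the *fixed* group labels.
We also ship the simpler one-shot scheme (`scheme = "residualize"`:
residualize once, shuffle labels) and a restricted-permutation
alternative (`scheme = "stratified"`: labels shuffled only within
sex-by-age-tertile strata).

The choice of Freedman–Lane as default is empirical and reproduced by
the shipped test suite: when the confounder is strongly associated with
the labels (vegan ages shifted by +1.5 years and an outcome that tracks
age), the one-shot scheme is noticeably conservative — its empirical
size falls markedly below the nominal 0.05, because the null-model fit
absorbs part of the label-aligned noise — while Freedman–Lane stays
near nominal. The validation suite verifies, on 500–1,000 replicate
simulations of exactly this design, that the unadjusted test is badly
inflated (rejection > 0.20), that the Freedman–Lane-adjusted test stays
within [0.03, 0.08], and that the one-shot scheme's size lies below
both.

Multiple testing uses Benjamini–Hochberg, applied **within** each
reported panel (anthropometrics; the biomarker panel; the enrichment set
collection) and never globally across panels, mirroring how such panels
are reported figure by figure.

Welch's unequal-variance t-test and the Behrens–Fisher
(Welch–Satterthwaite) confidence interval cover the cases where a
location difference on the measurement scale is the quantity of
interest, e.g. group differences of log fold changes.

## Untargeted metabolomics

Annotation is putative by design. Each observed ion m/z is matched
against a compound database using the deprotonated adduct
$[M-H]^-$ ($m/z = M - 1.007276$) at an **absolute** tolerance of
0.001 m/z, and *every* compound within tolerance is retained — isomers
share a monoisotopic mass and cannot be distinguished by accurate mass
alone. Only negative mode is modeled; the element-mass table
(C, H, N, O, P, S) is extensible. An annotation can gain support from an
isotopologue pattern: a companion peak at +1.003355 m/z (the
$^{13}$C–$^{12}$C spacing) whose intensities correlate with the
monoisotopic peak across participants (Pearson $r \ge 0.7$ by default).
Both the spacing and the correlation floor are configuration keys; the
flag is a deliberate simplification of full isotopologue deconvolution.

Fold changes are per-individual:
$\log_2(\text{intensity} / \text{arithmetic mean of the omnivore group})$,
so the omnivore mean is exactly the zero line. Zeros are replaced per
ion by half the smallest positive intensity before any log transform —
simple, order-preserving, and standard for FIA data. When several
related metabolites (say, three medium-chain fatty acids) are displayed
as one pooled box plot, the pooled group sizes multiply
(3 ions × 24 omnivores = 72), but **no** single test is computed on the
pooled values — pooled dependent metabolites violate the independence a
t-test needs — instead each member ion keeps its own Welch test with BH
correction across members.

## Set enrichment

Pathway-level analysis is the classic GSEA running sum: ions are ranked
by Welch t on log10 intensities between the two groups; walking down
the ranking, the sum rises by $|s_i|^p / \sum_{\text{members}} |s|^p$ at
set members and falls by $1/(N - N_m)$ otherwise; the enrichment score
is the signed maximal deviation (an exact tie between the positive and
negative extremes resolves to the positive one, a documented tie-break).
With $p = 0$ the walk ends exactly at zero. The default weight is
$p = 1$ and the minimum set size is 3.

The null distribution shuffles **sample labels**, not ion identities:
re-ranking after each shuffle preserves the inter-ion correlation
structure that FIA data certainly has, and on block-correlated synthetic
data the sample-permutation null is demonstrably wider than an
ion-shuffling null (an ion-shuffling mode exists behind the `null`
argument for speed, with that caveat). $p$-values are two-sided on
$|ES|$ with the add-one correction; $\mathrm{NES} = ES / \mathrm{mean}
(|ES^*|\ \text{of the same sign})$; BH across the retained sets. An ion
with several candidate annotations contributes to every pathway any
candidate belongs to — annotation ambiguity is propagated, not resolved.

## Clustering

Participants are clustered on log10-transformed, per-ion autoscaled
intensities (raw FIA intensities span orders of magnitude and would
otherwise be dominated by abundant ions; the transform is a package
choice, stated here because upstream conventions vary). Linkage is
agglomerative Ward. Two conventions circulate under that name: the
classic minimum-variance objective (Lance–Williams recurrence on
*squared* Euclidean distances, our default) and the same recurrence on
unsquared distances. Both are available via the `distance` argument,
and the convention used is recorded in the output, because published
descriptions are often ambiguous between the two. The tree is cut at a
fixed $k$ (default 4), clusters are relabeled A, B, … in participant
order, and composition tables report each cluster's diet-group mix and
each diet group's modal cluster.

For $n \le 8$ the package's merges are verified against an exhaustive
search that recomputes the within-cluster sum-of-squares increase of
every candidate merge from scratch.

## Growth-reference z-scores

Anthropometrics are standardized with the LMS (Box–Cox) method:
$z = ((x/M)^L - 1)/(LS)$ for $|L| > 10^{-8}$ and the log-limit
$z = \ln(x/M)/S$ otherwise; the branches agree to $<10^{-6}$ at the
switch and the inverse transform round-trips to $10^{-10}$ relative
error. Reference L/M/S values are interpolated linearly in age within
sex — at typical reference grid spacing the difference from spline
interpolation is far below 0.01 z. BMI is computed as weight/height²
(kg/m²) before z-scoring; we treat a BMI "SDS score" as the same LMS
transform. MUAC-for-age supports the two-table convention (one table to
5 years, an extended table above), with the boundary age belonging to
the younger table.

Reference tables are user-supplied CSVs. The packaged
`lms_synthetic.csv` is a synthetic fixture with smooth, plausible
pediatric trends — it is for testing and demonstration only and does not
reproduce any national or WHO reference.

## Micronutrient status rules

Cut-off classification follows one convention throughout: a boundary
value belongs to the *better* category, because pathology is defined as
falling below a cut-off. The shipped rules are serum RBP < 0.83 µmol/l
deficient and < 1.17 µmol/l insufficient; total 25(OH)D < 50 nmol/l
insufficient; erythrocyte folate outside 208–972 nmol/l flagged
below/above; transcobalamin-bound B12 right-censored at its 128 pmol/l
linear assay limit. Censored records are stored at the limit with a
flag, excluded from probability-index testing (a point mass at the
limit would make the test an artifact of the assay), and summarized as
the censored fraction per group. The inflammation-aware vitamin A
regression model (retinol estimated from RBP, transthyretin, and a CRP
transform) ships **unconfigured**: its published coefficients belong to
an external validation study, so `vitamin_a_model()` refuses to run
until the user supplies them; the default deficiency threshold for the
estimate is the conventional 0.70 µmol/l. The bile-acid conjugation
summary is the taurine-to-glycine ratio of summed conjugated
concentrations per participant, with a zero glycine sum yielding
`not_evaluable` rather than an error.

## The synthetic-cohort generator

The generator is first-class, tested code, and its defaults are the
study conditions everything else is validated under:

* **Design**: 24 omnivores, 10 vegetarians, 6 vegans; ages i.i.d.
  uniform on 1.42–7.07 years; sex Bernoulli(0.5). Uniform ages and
  balanced sex are the least-informative choices over a published range
  and count.
* **Metabolome**: 872 ions, log10 intensities multivariate normal with
  per-ion baselines uniform on [4, 6] (decades of abundance),
  within-group SD 0.15, and exchangeable within-pathway correlation
  0.3 implemented as a shared participant-level pathway factor. Group
  effects are specified per pathway on the log2 scale and converted to
  log10; the vegetarian shift is the vegan shift times an attenuation
  factor (default 0.5), encoding the intermediate vegetarian phenotype.
  An optional age slope adds confounding. The default effect table
  shifts one pathway up and one down by one log2 unit.
* **Biomarkers**: Gaussian (or log-normal) group-mean draws; vegan RBP
  centred at 0.95 µmol/l (below the insufficiency cut-off), vegan total
  25(OH)D at 60 ± 3.5 nmol/l (so ~95% of draws fall in 53–67), vegan
  folate mostly above the upper reference limit, and B12 means placed so
  that roughly two thirds of vegans and ~90% of omnivores exceed the
  128 pmol/l limit and are right-censored there.
* **Seeding**: one master seed is split into named substreams
  (cohort / metabolome / biomarkers / each test / enrichment), so adding
  a stage never perturbs earlier draws and every run is bit-reproducible.

What the generator does *not* emulate: real FIA spectra (no centroiding,
no adducts beyond [M−H]⁻, no heteroscedastic technical noise), skewed or
heavy-tailed biomarker distributions beyond the log-normal option,
missingness other than right-censoring, and any fitting of generative
parameters to real cohort data. Passing tests therefore demonstrate
that the *methods* behave correctly under the assumed structure — exact
oracle agreement, nominal size and coverage, planted-effect recovery —
not that real metabolomes satisfy the log-normal block model.

## Numerical choices and degenerate inputs

* Monte-Carlo p-values use the +1 correction; exhaustive p-values count
  the observed split, so neither can be zero.
* Null-distribution ties are counted with $\ge$ and a $10^{-12}$ float
  guard; the annotation tolerance carries a $10^{-9}$ guard so an
  exactly-at-tolerance match is kept.
* The Freedman–Lane scheme requires Monte-Carlo mode; in exhaustive
  mode only the one-shot residualization is offered, since the
  enumeration is over label splits, not residual permutations.
* Degenerate designs fail loudly: empty groups, rank-deficient
  covariate designs, all-zero ions, LMS queries outside the reference
  span, a vitamin A model without coefficients, more than
  $2\times10^5$ exhaustive splits.
* Enrichment sets with fewer than 3 members present are skipped with a
  warning; an all-zero score vector falls back to unweighted
  increments.

## Problem sizes used in validation

The shipped validation suite runs entirely on synthetic data at sizes
chosen to make Monte-Carlo error small relative to each validation
band: 1,000-replicate size checks at $B = 999$; a 50,000-draw
Monte-Carlo-versus-exhaustive sweep over all two-group designs with
$n \le 10$; 2,000-replicate interval-coverage checks; 500-ranking
enrichment-score oracle sweeps and 20 seeded power runs at $B = 999$;
50 seeded cohorts for the clustering recovery check (planted
|log2 shift| of 1.25 on 200 of 872 ions, i.e. 23% of the metabolome);
and two full default pipeline runs compared checksum-for-checksum. The
default pipeline run (47,500-permutation panel tests, 999-permutation
enrichment, full clustering) completes in well under a minute on one
CPU.

## Known limitations

* The probability-index test is pairwise only; no three-group omnibus
  test is provided.
* Annotation handles the [M−H]⁻ adduct only, and the isotopologue flag
  is a correlation heuristic, not a deconvolution.
* The LMS fixture is synthetic; real analyses must supply real
  reference tables.
* Status rules are deliberately simple threshold rules; they are not
  clinical decision support.
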