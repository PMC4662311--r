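---
title: "Methods: noninvasive genetic capture-recapture from scat surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: noninvasive genetic capture-recapture from scat surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`scatcap` implements the full analysis chain used to monitor a small,
closed carnivore population from fecal DNA: scats are collected along
search transects, assigned to species by an mtDNA fragment test, genotyped
at a microsatellite panel from replicate PCRs, clustered into individuals,
and the resulting individual-by-location capture histories feed a
spatially explicit capture-recapture (SECR) abundance model, while the
composite genotypes feed diversity, relatedness, inbreeding, and
effective-number-of-breeders estimators. This vignette explains each
model, its assumptions, the tunable parameters, and the numerical and
design choices behind the implementation.

## Species assignment

Sympatric bobcat and coyote scats are often morphologically
indistinguishable, but a conserved-primer mtDNA control-region fragment
differs in size between the species by 16 bp. `classify_species()` assigns
a scat to the species whose reference fragment length (defaults 180 bp and
196 bp) lies within `tolerance_bp` (default 3 bp, required to be less than
half the inter-species gap so windows cannot overlap). Failed reads and
fragments matching neither window are `UNKNOWN` and drop out of all later
stages — the same fate as degraded scats in a real survey.

## Consensus genotyping from replicate PCRs

Fecal DNA is low-template: heterozygotes lose alleles to *allelic
dropout*, spurious *false alleles* appear, and whole reactions fail. The
guard is replication. Each scat x locus is amplified in `n_replicates`
independent PCRs and `call_locus_consensus()` applies two asymmetric
rules:

* a **heterozygous** pair is accepted only if that exact unordered pair is
  seen in at least `min_obs` (default 3) successful PCRs;
* a **homozygous** call is accepted only if *every* successful PCR shows
  that single allele, and at least `min_obs` did.

Failed PCRs count neither for nor against; replicate order never matters.
The homozygote rule is deliberately stricter because a dropout-affected
heterozygote masquerades as a homozygote: a single discordant heterozygous
PCR is enough to veto the call. Two PCRs showing a pair plus one showing a
single shared allele do **not** combine into support — the full pair must
be seen in each supporting PCR (the strictest consistent reading; the
count threshold is configurable).

Scats amplifying at fewer than `min_amplified` (4) loci are screened out;
a scat is retained for identification only if it is the focal species and
carries accepted consensus calls at `min_consensus` (6) or more loci.
Both thresholds are the field defaults for this design and are exposed as
arguments.

## Individual identification

The 6-locus retention threshold is justified by the *probability of
identity*. For allele frequencies $p_i$ at a locus,

$$\mathrm{PID} = 2\left(\sum_i p_i^2\right)^2 - \sum_i p_i^4, \qquad
\mathrm{PID}_{sib} = 0.25 + 0.5\sum_i p_i^2 +
0.5\left(\sum_i p_i^2\right)^2 - 0.25\sum_i p_i^4,$$

multiplied across loci. $\mathrm{PID}_{sib}$ — the probability two *full
siblings* share a multilocus genotype — is the conservative criterion;
`pid_sib()` reports whether the cumulative value clears a threshold
(default $10^{-6}$). Both formulas are verified in the test suite against
brute-force enumeration over genotype (and parental mating) space.

`match_profiles()` compares two retained scats at their co-typed loci
(unordered-pair equality) and declares them the same animal when at least
`min_match` (5) loci match and at most `max_mismatch` (0) mismatch.
`cluster_scats()` takes the transitive closure of these decisions
(union-find), so matching is invariant to input order, and builds a
composite genotype per cluster by per-locus majority vote across member
scats, with ties resolved to missing. Clusters containing a DIFFERENT pair
(possible through transitive chaining) are flagged rather than silently
accepted.

Two design choices deserve comment. `max_mismatch = 0` is the
conservative default; real matching tools often tolerate one mismatching
locus when five match, so that mode is exposed (`max_mismatch = 1`).
And allele frequencies for PID, diversity and relatedness are computed
from the *composite individual* genotypes, not per scat — per-scat
frequencies would overweight animals that defecated more.

A structural limitation worth stating: genotype matching can only recover
*unique multilocus genotypes*. Individuals that share a full genotype
(possible among close relatives at a modest panel) are one "individual" to
any matching method, so the package's recovery tests compare against the
truth partition by unique genotype. Separately, when many heterozygous
calls fail consensus (high dropout, few successful PCRs), the loci that
would discriminate two close relatives may be missing from the co-typed
set, and relatives can merge. The exact-recovery calibration test
therefore pins the low-error, full-replication regime; under heavy error
the pipeline still runs but the individual count should be read as a count
of *distinguishable* genotypes.

## Population-genetic summaries

Per locus over typed individuals: observed heterozygosity $H_O$, expected
heterozygosity $H_E = 1 - \sum p_i^2$, Nei's small-sample unbiased
$uH_E = \frac{2n}{2n-1}H_E$, and allele count $A$. Allelic richness is
reported as the raw mean allele count (the "total number of alleles"
definition, not rarefied richness — the survey-tool convention this
package mirrors). Hardy-Weinberg deviation is tested per locus by
chi-square over all $k(k+1)/2$ genotype categories with
$df = k(k-1)/2$, with a seeded Monte Carlo exact alternative (alleles
permuted among genotypes, default 10,000 permutations; validated in the
tests against the exact Levene conditional distribution). The chi-square
approximation can differ noticeably from the exact p at mid-range
p-values for moderate samples; the default remains chi-square for parity
with standard survey tools. $F_{IS} = (H_E - H_O)/H_E$ per polymorphic
locus, averaged unweighted; negative values mean heterozygote excess.

### Effective number of breeders

Two single-sample estimators:

* **Heterozygote excess.** When few breeders produce a cohort, binomial
  sampling of parental alleles inflates heterozygosity. With per-locus
  $D_\ell = (H_{O,\ell} - H_{E,\ell})/H_{E,\ell}$ and the mean weighted by
  the number of independent alleles ($k_\ell - 1$, the convention of the
  standard estimation tool; an unweighted mean is also reported),
  $$N_b = \frac{1}{2\bar D} + \frac{1}{2(\bar D + 1)},$$
  with $N_b = \infty$ when $\bar D \le 0$ (no excess, no information).
  The CI is a jackknife over loci on the $D$ scale, transformed.
* **Molecular coancestry.** Pairwise similarity
  $f_0 = \tfrac14[I(a{=}c) + I(a{=}d) + I(b{=}c) + I(b{=}d)]$ exceeds
  identity-in-state by $(1-s)/(2N_b)$ in a single cohort from $N_b$
  random-mating unrelated breeders. Identity-in-state $s$ is estimated
  per locus by the cohort's *within-individual* identity (observed
  homozygote fraction) — using sample allele frequencies instead would
  absorb the drift signal and always return $\infty$. Then
  $f_1 = \langle (f_0 - s)/(1 - s)\rangle$ and $N_b = 1/(2 f_1)$.
  Exact numerical parity with external implementations is not claimed;
  the estimator is validated by parameter recovery on simulated cohorts
  of known parent number.

Both assume a discrete cohort of offspring; applied to a standing
population of mixed generations (as any scat survey is), they are
indicative rather than strictly model-true — the same caveat the original
field design carries.

## Relatedness and inbreeding

Pairwise relatedness uses the standard non-inbred dyad likelihood. A dyad
shares 0, 1, or 2 alleles identical by descent with probabilities
$k = (k_0, k_1, k_2)$; per locus
$P(g_1, g_2 \mid k) = k_0 P_0 + k_1 P_1 + k_2 P_2$ with $P_0$ the product
of Hardy-Weinberg genotype probabilities and $P_1, P_2$ the standard
one-/two-IBD terms for unordered genotypes; log-likelihoods sum over
co-typed loci. The tests verify this table against Monte Carlo frequencies
of dyads simulated directly from the IBD process.

`estimate_r_ml()` maximizes over the whole $k$ simplex (no
$k_1^2 \ge 4k_0k_2$ constraint, matching the reference tool's default;
the constraint would only matter for pathological data) by a 0.01-step
grid search plus 0.001-step local refinement, guaranteeing the returned
optimum is at least as good as every coarse-grid point; likelihood ties
break toward smaller $r = k_1/2 + k_2$. Genotyping error in the
likelihood is fixed at zero (the analysis this mirrors did not report
using an error parameter). `classify_relationship()` evaluates the four
anchors U $(1,0,0)$, HS $(\tfrac12,\tfrac12,0)$, FS
$(\tfrac14,\tfrac12,\tfrac14)$, PO $(0,1,0)$ and breaks ties toward the
less related category. Note the known upward boundary bias of ML
relatedness for truly unrelated dyads: $\hat r \ge 0$ by construction, so
its mean is positive and grows as the panel loses alleles or loci; the
recovery tests use 12-locus equifrequent panels (5 alleles for mean-$r$
recovery, 4 for PO classification) where the estimator's expected
behavior is well characterized.

Individual inbreeding maximizes over $F \in [0,1]$ the product of
$P(aa\mid F) = p_a^2 + F p_a(1-p_a)$ and
$P(ab\mid F) = 2 p_a p_b (1-F)$ across typed polymorphic loci (at least
3 required), with a percentile bootstrap over loci (default 100
replicates) for the CI. This is a single-individual ML estimator; the
triadic three-reference estimator of the original analysis is a property
of that external tool and is deliberately out of scope — the published
pairwise table itself ships with the package (`published_study()`) and the
desk-scale checks reproduce its summaries exactly.

## SECR abundance

Transect polylines are cut into `section_length` (200 m) sections
measured along the path; a final remainder longer than half a section
stands alone, otherwise it merges into the previous section, and each
section's along-path midpoint is a binary *proximity detector*. Scats
snap to the nearest detector (ties to the lowest id; beyond `max_snap`,
500 m, they are excluded with a warning), and repeated detections of one
individual at one detector x occasion collapse to a single binary entry.
Occasions are taken from the detection records (the shipped generator
uses K = 2, two passes per transect); for undated real scats a
first-pass/second-pass mapping must be supplied upstream.

With half-normal detection $p_j(x) = g_0 \exp(-d_j(x)^2/2\sigma^2)$ and a
habitat mask of cell area $a$ (habitat polygon discretized at
`resolution`, default 250 m; without a polygon, a rectangular buffer
around the detectors, default 4 spatial scales), the homogeneous-Poisson
log-likelihood is

$$\log L = -D \sum_x p_\cdot(x)\,a + \sum_i \log\Big[D \sum_x
\Pr(\omega_i \mid x)\,a\Big],$$

where $p_\cdot(x) = 1 - \prod_{j,k}(1 - p_j(x))$. `fit_secr()` maximizes
over $(\log D, \operatorname{logit} g_0, \log\sigma)$ with Nelder-Mead
(relative tolerance $10^{-10}$, up to 2,000 iterations), takes standard
errors from the inverse numerical Hessian on the link scale,
back-transforms Wald intervals, and reports $\hat N = \hat D \cdot A$
with a delta-method SE. Starting values: $D_0 = n/A$, $g_0 = 0.1$,
$\sigma_0$ = half the mean inter-detection distance. Underflowed
detection probabilities are clamped before logs so undetected
detector-cell pairs contribute exactly zero. The likelihood is verified
in the tests against brute-force summation on tiny masks, and two
stability properties are enforced: halving the mask cell size changes the
log-likelihood by less than 0.01 at the fixture's spatial scale, and for
buffered masks the *density* estimate moves by under 2% when the buffer
grows from 4 to 6 sigma (abundance for a buffered mask is $D$ times the
growing mask area, so density is the invariant; with a fixed habitat
polygon, as here, $\hat N$ itself is the meaningful total).
$\hat N \ge n$ holds at the MLE by construction of the Poisson form.

## The synthetic generator

`simulate_scat_survey()` produces everything the pipeline consumes, plus
truth tables. Defaults are the study-scale conditions: 12 polymorphic
loci with 3-5 alleles (Dirichlet-drawn founder frequencies from a fixed
internal stream), a 9-animal population (5 founders + 4 offspring,
yielding unrelated, full-sib, half-sib and parent-offspring dyads),
activity centers uniform over a 3.5 x 20 km island-like polygon (7,000
ha), three lengthwise transects searched twice, half-normal detection
with $\sigma$ = 770 m and $g_0$ = 0.22 per detector-occasion, four PCRs
per scat x locus, dropout 0.10, false alleles 0.02, and a scat-quality
mixture (45% degraded scats failing 90% of PCRs, intact scats failing
15%). The mixture is what reproduces, simultaneously, per-locus
amplification rates in the tens of percent *and* a usable core of scats
with near-complete multilocus genotypes — a single failure rate cannot do
both. Under these defaults a simulated survey yields on the order of
40-50 identifiable bobcat scats of which roughly 20 pass the 6-locus
filter, about 46 coyote scats, and a fifth of fragment reads fail —
the scale of the motivating survey.

What the generator does *not* emulate: territorial spacing and
home-range dynamics (centers are uniform, as the SECR model assumes),
transect-choice bias, within-scat DNA heterogeneity beyond the two-class
quality mixture, scat decay between occasions, and interspecific
interference. Passing recovery tests therefore demonstrate correctness of
the estimators under their own assumptions, not robustness to these field
realities.

Problem sizes in the shipped tests were chosen to keep each recovery
study statistically meaningful at desk scale: 100 simulated surveys for
SECR parameter recovery and CI coverage (300 m mask for speed), 1,000
dyads per relationship category, 1,000 selfed individuals for inbreeding
recovery, 200 seeded surveys for the identification calibration property,
and 100 cohorts for coancestry-$N_b$ recovery.

## Reproducing the published island results

The deposited survey data (per-scat genotypes, scat GPS locations,
transects, island boundary) are archived externally. When a converted
copy is placed under `inst/extdata/dryad/` (`genotypes.csv` in the
two-columns-per-locus dialect, `transects.geojson`, `habitat.geojson`,
`detections.csv`), the acceptance suite re-runs identification,
diversity, and the SECR fit against the published values (9 individuals,
$H_O$ = 0.742, AR = 3.67, $F_{IS}$ = -0.255, $\hat N$ = 14.41,
$\hat\sigma$ = 772.9 m, 749 detectors). Without it, only the printed
pairwise-relatedness table and summary numbers (shipped with the
package) are reproducible, and that acceptance check reports failure
rather than silently passing.
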