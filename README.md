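# scatcap — noninvasive genetic capture–recapture from scat surveys

`scatcap` is an R package plus analysis workflow for estimating the
abundance, effective population size, genetic diversity, relatedness and
inbreeding of a small, closed carnivore population from fecal DNA — the
monitoring design used for insular or reintroduced felid populations,
where scats collected along search transects are the only practical
source of individual identity. It is written for wildlife geneticists and
quantitative ecologists who need the whole chain, from raw replicate-PCR
allele calls to a spatially explicit abundance estimate, in one tested,
reproducible place.

## What it computes

* **Species assignment** from an mtDNA control-region fragment length
  (sympatric species differ by a diagnostic 16 bp).
* **Consensus microsatellite genotypes** from replicate PCRs under the
  standard low-template rules: a heterozygous pair is accepted only when
  observed in ≥ 3 successful PCRs; a homozygote only when every
  successful PCR shows that single allele; scats are retained at ≥ 6
  consensus loci (≥ 4 amplifying loci to pass screening).
* **Individual identification**: probability of identity
  `PID = 2(Σp²)² − Σp⁴` and its full-sibling analogue
  `PIDsib = 1/4 + (Σp²)/2 + (Σp²)²/2 − (Σp⁴)/4`; scats match when ≥ 5
  co-typed loci agree; union-find clustering with majority composite
  genotypes.
* **Diversity**: Ho, He = 1 − Σp², unbiased uHe = 2n/(2n−1)·He, allele
  counts, chi-square and Monte Carlo exact Hardy–Weinberg tests,
  FIS = (He − Ho)/He.
* **Effective number of breeders**: heterozygote excess
  `Nb = 1/(2D̄) + 1/(2(D̄+1))` with D̄ the (k−1)-weighted mean of
  (Ho−He)/He, and a single-cohort molecular-coancestry estimator
  `Nb = 1/(2f₁)`.
* **Relatedness and inbreeding**: maximum-likelihood k-vector estimation
  over the IBD simplex (r = k₁/2 + k₂), U/HS/FS/PO classification, and
  ML individual F with locus-bootstrap CIs.
* **SECR abundance**: transects cut into 200 m sections whose midpoints
  are binary proximity detectors, half-normal detection
  `g(d) = g₀·exp(−d²/2σ²)`, and the homogeneous-Poisson SECR likelihood
  integrated over a habitat mask, maximized on link scales with
  Hessian-based SEs and `N̂ = D̂·A`.
* **A synthetic scat-survey generator** (pedigree, spatial, and PCR-error
  models with truth tables) so every stage is exercisable and testable
  without the original field data.

The methods vignette (`vignettes/scat-survey-methods.Rmd`) documents the
models, assumptions, parameter defaults and numerical choices.

## Worked example

The numbered scripts under `analysis/` run the full chain on a synthetic
survey generated at the motivating study's scale (9 bobcats on a 7,000 ha
island, three transects searched twice, 12 microsatellite loci, four PCRs
per scat × locus):

```sh
Rscript analysis/01_simulate_survey.R 1     # raw files -> results/synthetic/
Rscript analysis/02_consensus_genotyping.R
Rscript analysis/03_identify_individuals.R
Rscript analysis/04_popgen_diversity.R
Rscript analysis/05_relatedness_inbreeding.R 1
Rscript analysis/06_secr_abundance.R
Rscript analysis/07_published_table_checks.R
```

With seed 1 this prints, stage by stage:

```
Simulated survey (seed 1): 112 scats collected along 3 transects;
  66 from the 9 bobcats (activity centers in a 7000 ha island), 46 from coyotes.
Species assignment: 55 bobcat, 35 coyote, 22 unknown scats.
25 of 112 scats retained with consensus genotypes at >= 6 loci.
Identified 9 individuals from 25 retained scats (2.8 scats each);
Cumulative PID(unrelated) = 1.9e-07, PID(sib) = 0.000655 (below 1e-6: FALSE)
Diversity over 12 loci: mean Ho = 0.622 (SE 0.053), mean uHe = 0.593, AR = 2.92.
Mean FIS = -0.143 (negative = heterozygote excess); min HWE p = 0.047.
Effective breeders: heterozygote excess 6.1 (D = 0.089), coancestry Inf.
Pairwise r over 36 pairs: mean 0.177 (SD 0.292); 27 near zero, 9 >= 0.5.
SECR fit (half-normal, binary proximity): 9 individuals, mask 7000 ha
N-hat = 10.08 (SE 3.413, 95% CI 5.2-19.6), logLik = -123.133
```

Reading it: of 112 simulated scats, 55 type as bobcat by fragment length
and 25 survive the 6-locus consensus filter; clustering those 25
recovers 9 distinct genotypes (the simulated population holds 9 animals);
a per-locus PIDsib product of 6.6e-4 says this particular synthetic
locus panel is *not* discriminating enough to clear the 1e-6 sibling
criterion — exactly the diagnostic the threshold exists for; the
individuals show heterozygote excess (negative FIS), as expected for a
cohort descending from few breeders, and the heterozygote-excess
estimator turns that excess into ≈ 6 effective breeders; the SECR fit
integrates the 9 capture histories over the island mask and estimates
about 10 animals (truth: 9) with σ ≈ 980 m. Stage outputs (per-locus
tables, matrices, fit JSON) land under `results/`.

`run_pipeline()` performs the same chain in one call (simulated or
file-based inputs) and writes a consolidated `report.json`/`report.txt`.

### Input formats (real data)

Replicate calls: CSV `scat_id,pcr_id,locus_id,allele_a,allele_b`, alleles
as integer fragment sizes, `0,0` = failed PCR, `a,a` = single allele
observed. Genotype tables: one column of sample ids then two columns per
locus, missing = `0,0`. Fragments: CSV `scat_id,fragment_bp`. Detections:
CSV `scat_id,x,y,occasion` (projected planar meters, 1-based occasions).
Transects/habitat: GeoJSON LineString/Polygon (or `transect_id,x,y` /
`polygon_id,x,y` CSV). No CRS transformation is performed — project
coordinates before import; external deposits in shapefile form should be
converted to GeoJSON with any standard GIS tool.

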