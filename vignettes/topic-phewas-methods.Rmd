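---
title: "Topic-based PheWAS: models, parameters and design choices"
author: "topicPheWAS authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topic-based PheWAS: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topicPheWAS)
```

## The problem

A phenome-wide association study (PheWAS) asks what phenotypes a single
genetic variant is associated with, scanning the diagnostic history of a
genotyped cohort. Testing each of the thousands of individual billing
codes separately both inflates the multiple-testing burden and inherits
the unreliability of single codes. This package implements the
topic-model alternative: summarise each subject's diagnostic history
into a small number of *topics* — groups of codes that co-occur across
the cohort — and test each topic's per-subject membership score as a
quantitative trait. Only topics passing an experiment-wide threshold are
then unpacked into their constituent codes.

The pipeline has five stages, each an exported function:

1. **Rollup and filtering** (`mapCodes`, `frequencyFilter`): raw ICD-9
   codes are rolled up to top-level PheWAS codes via a user-supplied
   mapping table, and codes present in fewer than 0.5% of subjects are
   eliminated.
2. **Topic model** (`fitLda`): latent Dirichlet allocation over the
   subject-by-code count matrix, treating each subject's record as a
   document of code tokens; K = 50 topics by default.
3. **Per-wave association** (`runTopicScan`): within each genotyping
   wave, ordinary least squares of each topic score on allele dosage
   (additive coding 0–2), adjusted for the first 10 principal
   components.
4. **Meta-analysis** (`fixedEffectsMeta`): waves pooled with
   inverse-variance weights; significance against the Bonferroni
   threshold 0.05/K (0.001 for 50 topics), strict inequality.
5. **Code-level follow-up** (`runCodeScan`): for each significant
   topic, presence/absence of every code with topic weight ≥ 0.01 is
   tested by logistic regression per wave, PC-adjusted and then
   PC+BMI-adjusted, pooled the same way, and assembled into a report
   table alongside per-wave odds ratios.

Waves are analysed separately and meta-analysed — never pooled into one
regression — because genotyping batches were cleaned and imputed
separately and may carry batch effects. The topic model itself is fitted
once on the full matrix (all waves); only the association stage is
stratified.

## The LDA model and its sampler

Each subject i has topic weights $\theta_i \sim \mathrm{Dir}(\alpha)$,
each topic k a code distribution $\phi_k \sim \mathrm{Dir}(\beta)$, and
each code token is drawn topic-first:
$z \sim \mathrm{Cat}(\theta_i)$, $w \sim \mathrm{Cat}(\phi_z)$. A count
of c for one code contributes c separate tokens.

Inference is collapsed Gibbs sampling over token-level topic
assignments. After burn-in, posterior means are averaged over retained
sweeps:

$$\hat\phi_{kv} = \frac{n_{kv} + \beta}{n_k + V\beta},\qquad
  \hat\theta_{ik} = \frac{n_{ik} + \alpha}{n_i + K\alpha}.$$

Numerical and design choices:

* **Defaults** `nIterations = 500`, `burnIn = 200`, `thin = 10`
  (30 retained sweeps). The collapsed log-likelihood trace is stored in
  the fit for convergence inspection; it is monitored in trend, not
  asserted per sweep, since individual Gibbs sweeps may decrease it.
* **Priors** symmetric $\alpha = 50/K$ and $\beta = 0.1$, the common
  defaults for LDA on count matrices; both are exposed as arguments.
* **K = 50** is a convention carried over from prior applications of
  topic models to diagnostic codes; there is no well-established
  selector for K and the package deliberately offers none.
* **Zero-code subjects** are retained; their score row is exactly the
  prior mean 1/K (set explicitly, not left to floating-point
  cancellation). Excluding them would silently change the cohort.
* **Determinism and equivariance.** The sampler uses R's RNG, so a
  fixed seed reproduces the fit bit-identically on the same platform.
  The token stream is canonicalised by subject id and code string
  before sampling, so permuting the rows or columns of the input matrix
  permutes the output without changing any number. The same
  id-canonical ordering is applied at the subject join in the pipeline,
  which is why shuffling input file row order leaves every output table
  byte-identical.
* **Label switching.** Topic indices are arbitrary. Every comparison
  against a reference (including all recovery tests) first aligns
  topics greedily by cosine similarity of the $\phi$ rows
  (`matchTopics`); nothing downstream depends on raw topic order.

## Association and pooling

Topic scores are bounded in (0, 1) and right-skewed, not Gaussian; the
OLS Wald t test is nevertheless well calibrated at wave sizes in the
hundreds (the type-I error acceptance test verifies this directly at
n = 500 per wave). The per-allele effect on a topic score is therefore
interpretable as a difference in expected topic membership per minor
allele.

The logistic follow-up applies a minimum-support rule before fitting:
fewer than `minCases = 10` cases in a wave, fewer than 10 controls, or
fewer than 10 cases among minor-allele carriers all mark the wave
`skipped_low_frequency` — the "frequency too low for regression result"
entries of a per-wave report. Complete separation is detected from the
IRLS warnings plus a diverging coefficient and flagged
`failed_separation` with no estimate, rather than reporting a
meaningless huge OR. Skipped waves are excluded from the pool;
`n_waves_used` records how many contributed. p-values are floored at
the smallest positive double, never reported as exactly zero.

The fixed-effects pool uses weights $w_i = 1/\mathrm{se}_i^2$; Cochran's
Q on `n_waves_used − 1` df is reported as a heterogeneity diagnostic —
an extension beyond the pooled test itself, included because it is
cheap and flags waves that disagree.

Boundary conventions, chosen once and tested: a code present in exactly
0.5% of subjects is *retained* (the filter eliminates strictly
sub-threshold codes); a pooled p exactly equal to the Bonferroni
threshold is *not* significant (strict `<`); follow-up code selection
uses weight `>= 0.01` by default with the strict comparison available
as an option, since the two conventions appear interchangeably in
practice.

## The synthetic cohort generator

Real biobank data cannot ship with a package, so `simulateCohort` /
`simulateCodeCounts` generate a cohort from the exact model family the
analysis assumes, with a planted effect whose recovery is the
package's end-to-end acceptance surface. The generator's defaults are
the study conditions:

| parameter | default | rationale |
|---|---|---|
| wave sizes | 360 / 333 / 355 / 310 | 1/10 of the four genotyping waves of the motivating cohort |
| `maf` | 0.079 | the study variant's minor allele frequency; genotypes are Binomial(2, maf), i.e. Hardy-Weinberg proportions |
| `nTopicsTrue` | 10 | desk-scale topic count: large enough for a nontrivial multiple-testing burden, small enough to fit in seconds |
| `nCodes` | 60 | keeps tokens-per-code high enough for recovery at these sample sizes |
| `alpha0` | 0.5 | sparse mixed records: subjects concentrate on a few topics, as real diagnostic histories do |
| `betaPhi` | 0.1 | topics concentrated on a modest subset of codes |
| `effectSize` | 1.0 | per-allele shift of the risk topic's Dirichlet concentration; calibrated in a pilot to give high power at the default sizes, so the recovery acceptance test measures the pipeline, not the generator |
| `codesPerSubjectMean` | 30 | Poisson document length, floored at 1 (no subject enters a biobank without a single code) |
| `bmiMean`, `bmiSd` | 27.6, 6.1 | cohort BMI distribution |
| `bmiGenotypeSlope` | 0.5 kg/m² per allele | the variant's known BMI association, so BMI adjustment in the follow-up is exercised against a real confounding path |

The genotype effect enters the Dirichlet concentration *additively per
allele* ($\alpha_{i,\text{risk}} = \alpha_0 + \delta\,d_i$), mirroring
the additive allelic regression downstream; with `effectSize = 0` the
risk topic is exchangeable with every other topic, which is what the
null-calibration tests rely on. Principal components are independent
standard normals by default — they adjust for nothing, which is the
point: under the null the adjusted test must keep its size. An optional
`pcConfounding` mode couples PC1 to both the genotype frequency and the
risk topic for stratification stress tests, and `dosageNoiseSd`
emulates imputed fractional dosages (the association code accepts
either; hard calls are the default since the analysis treats dosage
linearly in both cases).

What the generator deliberately does **not** emulate: linkage
disequilibrium and genome-wide structure, a realistic ICD-9 ontology
(codes are an unstructured vocabulary), within-family relatedness,
differential record length by health status, and miscoding. Passing
tests therefore demonstrate that the pipeline recovers what it assumes
— an LDA-structured phenome with an additive effect — not that LDA is
the right model for any particular health system's records.

## Problem sizes used in the test suite

The automated checks run at deliberately small scale, chosen as the
smallest sizes at which the statistical claims are stable: type-I error
calibration uses 1000 meta-analysed replicates of 4 × 500 subjects;
planted-effect recovery uses 50 full pipeline replicates at the default
1/10-scale wave sizes (about 1360 subjects, 10 topics); topic-recovery
fidelity uses a 500-subject, 5-topic, 50-code corpus with
well-separated topics (`betaPhi = 0.05`). The acceptance script
(`scripts/acceptance.R`) re-measures the same quantities from scratch
at the same sizes.

## Known limitations

* Collapsed Gibbs is exact only in the limit; with 500 sweeps the
  posterior means carry Monte-Carlo noise of a few percent, which the
  alignment-based tests absorb. Variational inference is out of scope.
* The pipeline is single-variant by design; a genome-wide loop, mixed
  models, kinship adjustment and FDR procedures are non-goals.
* The prevalence filter and the report-table frequencies are computed
  on the pooled cohort, not per wave; with very unbalanced waves a code
  can pass the pooled filter while being absent from a small wave (the
  per-wave minimum-case rule then handles it).
* `PhewasCodeMap` ships no real phecode table; `truncationCodeMap`
  provides only a crude three-character rollup for synthetic
  vocabularies.
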