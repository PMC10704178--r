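---
title: "Rare-variant burden and gene-collapse association testing with exact inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant burden and gene-collapse association testing with exact inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvburden)
```

## The analysis problem

`rvburden` implements a candidate-gene rare-variant association analysis for
small pharmacogenetic cohorts. The motivating setting is epilepsy patients
treated with perampanel, an AMPA-receptor antagonist: exome genotypes over
the 26 human glutamate-receptor genes (HGNC families `GRIA1-4`, `GRID1-2`,
`GRIK1-5`, `GRIN1`/`GRIN2A-D`/`GRIN3A-B`, `GRM1-8`) are tested against four
dichotomized treatment outcomes — seizure response, any adverse drug
reaction (ADR), behavior ADR (irritation, aggression or psychotic symptoms;
by definition a subset of ADR), and 1-year retention on the drug.

With a cohort of under a hundred patients, single-variant tests are
hopeless. The package therefore aggregates qualifying variants at two
levels:

* **Burden analysis.** Per patient, count qualifying variant sites in a gene
  set (the whole 26-gene panel, or one of the five receptor families) and
  compare the counts between outcome-present and outcome-absent patients
  with the Mann–Whitney $U$ test.
* **Collapse analysis.** Per gene, dichotomize each patient as carrier
  (at least one qualifying variant) versus non-carrier and test the 2×2
  carrier-by-outcome table with the Fisher exact test, reporting the
  conditional maximum-likelihood odds ratio $\hat\psi$ and an exact
  confidence interval.

A variant *qualifies* when its reference-population alternate-allele
frequency is at most `maf_threshold` (default 0.05, inclusive) **or** it is
absent from the frequency resource, its consequence is not a synonymous
SNV, and its gene belongs to the catalog. A variant missing from the
population resource is treated as rare: anything that has never been
catalogued is rarer than any threshold, and discarding novel variants would
be the worse error in a rare-variant design.

## Exact inference on 2×2 tables

All collapse-test inference conditions on the table margins. With row
totals $r_1, r_2$ (outcome present/absent), first-column total $c_1$
(carriers) and odds ratio $\psi$, the carrier-with-outcome cell $A$ follows
Fisher's noncentral hypergeometric distribution

$$
P(A = k \mid \psi) \;=\;
\frac{\binom{r_1}{k}\binom{r_2}{c_1-k}\,\psi^k}
     {\sum_u \binom{r_1}{u}\binom{r_2}{c_1-u}\,\psi^u},
\qquad k \in [\max(0, c_1-r_2),\, \min(r_1, c_1)].
$$

* `fisher_two_sided_p()` sums the central ($\psi = 1$) probabilities of all
  tables no more probable than the observed one (the minimum-likelihood
  rule). This is the dominant software convention, and it is the convention
  under which a table can have $p < 0.05$ while the central exact CI spans 1
  — a combination the reference results exhibit.
* `conditional_mle_or()` solves $E[A \mid \psi] = a$. The conditional mean
  is strictly increasing in $\psi$ on the interior of the support, so the
  root is unique; it is found by bracket expansion and bisection on
  $\log\psi$ to a relative tolerance of $10^{-10}$. At the support
  boundaries the estimate is $0$ or $\infty$, flagged rather than smoothed
  by continuity corrections. The conditional MLE is slightly shrunk
  relative to the sample cross-product ratio (e.g. 4.64 versus 4.75 on the
  fixture's GRIN3A table), which is exactly the signature of published
  exact-test odds ratios.
* `exact_or_ci()` inverts the tails: the lower endpoint solves
  $P(A \ge a \mid \psi) = (1-\text{level})/2$ and the upper endpoint
  $P(A \le a \mid \psi) = (1-\text{level})/2$. Endpoints are converged to
  $10^{-10}$ on $\log\psi$; the residuals of the defining equations are
  checked to $10^{-8}$ in the test suite. Because the equations are solved
  to convergence, the upper GRIN3A endpoint is 18.956, which rounds to
  18.96 rather than the 18.97 printed by software that stops its root
  search earlier; the discrepancy is in the fourth significant digit.

The Mann–Whitney implementation (`mann_whitney_u()`) uses pooled midranks.
Exact p-values come from the permutation distribution of $U$ given the
pooled multiset: a subset-sum counting recursion over ranks when there are
no ties, full enumeration of labelings when there are. The exact two-sided
p-value is the doubled smaller tail (observed value included), capped at 1.
The `auto` mode uses the exact path for untied pooled samples of at most
25; otherwise the normal approximation with tie-corrected variance and a
continuity correction (matching `wilcox.test(correct = TRUE)`). Burden
counts are heavily tied, so the approximation is the path actually taken at
cohort scale; the exact path matters for small strata and for verification.

### The companion logistic odds ratio

Published burden analyses often print an odds ratio next to the
Mann–Whitney p-value without stating its derivation, and such values are
generally not reconstructible from the test statistic. `rvburden` does not
guess: `burden_or_logistic()` fits outcome ~ intercept + count by binomial
maximum likelihood and reports `exp(slope)` per unit count with a Wald
interval, clearly labeled as a descriptive companion. Significance calls
always come from the Mann–Whitney p-value. Complete separation (the two
outcome groups' counts have disjoint ranges) is detected exactly for this
single-covariate model and flagged with an infinite or zero odds ratio and
no interval.

## Multiple testing

Bonferroni correction is applied per analysis family, per outcome, by
thresholding: the five receptor-family burden tests form a family of 5
(threshold $0.05/5 = 0.01$), and the 26 gene-collapse tests a family of 26
(threshold $0.05/26 = 1.92\times10^{-3}$). The whole-panel burden test is
its own single-test family and is reported at the nominal level. Families
are not pooled across the four outcomes — this matches the thresholds the
reference analysis states. Genes with no carriers are reported as
*untestable* (`NA` statistics) rather than $p = 1$; they still count toward
the family size of 26, keeping the threshold honest. Both the family
threshold and `min(1, m·p)` are carried in the in-memory results; the
12-column output schema reports the threshold.

## Input contracts

Variant identity is the canonical key `chrom:pos:ref:alt` in 1-based VCF
coordinates; inputs are assumed pre-normalized (no left-alignment is
attempted). Multi-allelic sites are split into one record per alternate
allele, with a `1/2` genotype contributing one allele to each split record,
so total alternate dosage is conserved. Genotypes are read from the GT
field only, diploid, with `./.` treated per `missing_genotype_policy`
(default: as homozygous reference, with a logged count; the strict policy
aborts instead). Consequence annotation uses a closed vocabulary —
`synonymous_snv`, `missense_snv`, `nonframeshift_substitution`,
`frameshift`, `stop_gain`, `splice`, `other`, `unannotated` — because the
qualification filter hinges on cleanly separating synonymous SNVs from
retained classes such as non-frameshift substitutions. Phenotypes are
strictly binary with the behavior-ADR ⊆ ADR nesting enforced at load time;
no covariates are modeled.

Patient order is canonicalized (sorted IDs) on load, which makes the whole
pipeline — including the iteratively fitted companion logistic model —
byte-identical under permutations of VCF sample columns or phenotype rows.

## The synthetic cohort generator

`simulate_cohort()` generates cohorts with the statistical structure the
analysis assumes, no more:

* Outcomes are Bernoulli at configured marginal prevalences; defaults are
  the reference cohort's 14/83 (response), 22/83 (ADR), 14/83 (behavior
  ADR) and 61/83 (retention). Behavior ADR is drawn as a sub-event of ADR
  with conditional probability chosen to hit its marginal. Outcomes are
  otherwise independent — no joint distribution beyond the nesting is
  available to emulate.
* Carrier status per gene is Bernoulli with baseline probability
  `per_gene_carrier_freq` (default 0.10 per gene, a realistic aggregated
  rare-non-synonymous carrier frequency for large receptor genes; the two
  genes with published counts carry at 11/83 and 19/83). The carrier logit
  is shifted by $\log(\text{OR})$ for outcome-positive patients per the
  effect map, so the configured OR is exactly the carrier-by-outcome odds
  ratio the collapse test estimates. Each carrier receives one heterozygous
  variant at a uniformly chosen site of the gene.
* Sidecar frequencies come from `maf_generator` (default Uniform(0, 0.05),
  so every simulated site qualifies and the generative carrier model is
  what the pipeline sees).

What the generator deliberately does **not** emulate: linkage
disequilibrium, population stratification, a realistic site-frequency
spectrum, compound heterozygotes, sequencing error or genotype missingness
(unless configured). Passing simulation tests therefore validates the
statistical machinery under the stated generative model, not robustness of
the study design to real-exome artifacts.

`paper_fixture()` is deterministic, not simulated: 83 patients with the
reference outcome counts and the seven published GRID1/GRIN3A variants
assigned to distinct patients with their published carrier splits. The
published tables fix only margins, so the assignment makes the most neutral
choices available: behavior-ADR patients are P001–P014 inside the ADR block
P001–P022; GRID1's ADR carriers are placed in the non-behavior stratum so
the fixture does not invent a GRID1/behavior-ADR association; the response
and retention index sets are spread evenly across carriers and
non-carriers. One variant per patient is likewise an assumption — the
reference tables do not disclose compound carriers — surfaced here rather
than hidden. Under it, the fixture's GRIN3A table is (7, 7; 12, 57) and
reproduces the published OR 4.64, CI (1.16, 18.97) and p = 0.0143;
the reconstructed GRID1 table yields OR 6.46 rather than the published
5.54, which is not recoverable from any table the published counts support
and is treated as non-reproducible.

`recovery_experiment()` wires the generator to the collapse machinery for
type-I-error and coverage studies. Replicates run through the same
qualification/collapse/inference functions as the file pipeline but on
in-memory cohorts; emitting and re-parsing the file triple per replicate
would only re-exercise the I/O layer, whose fidelity is pinned by a
dedicated byte-level round-trip test.

## Numerical and design choices

* Root-finding is deterministic bisection on $\log\psi$ (no randomness, no
  derivative approximations); two-sided Fisher ties in the
  minimum-likelihood rule are compared with a $1+10^{-7}$ relative guard,
  matching common practice.
* Qualification reasons are assigned with precedence no-gene →
  not-in-catalog → synonymous → MAF; the pass/fail verdict itself is
  precedence-free.
* Homozygous alternates count once toward carrier status and, by default,
  once toward burden (`distinct_sites`): "number of rare variants" is read
  as variant sites, and published per-variant tables count carriers. The
  `allele_dosage` mode is available behind a flag; the choice is a
  documented open question of the source data, not a statistical necessity.
* Burden families and thresholds are fixed by the catalog (5 groups, 26
  genes) regardless of which genes happen to be testable in a given cohort.
* Test problem sizes were chosen to pin the numerics tightly at small
  scale: exhaustive Fisher verification over all tables with $n \le 30$,
  permutation verification of the exact Mann–Whitney for pooled $n \le 10$,
  200 random tables for the estimator/CI equations, 2000 null replicates at
  $n = 83$ for type-I error and 400 replicates at $n = 830$ for CI
  coverage.

## Known limitations

* Only diploid autosomal-style genotypes are handled; sex-chromosome
  ploidy is not special-cased.
* No variant weighting (MAF or deleteriousness weights) and no
  variance-component (SKAT-style) tests: the methods are deliberately the
  unweighted count and presence/absence analyses.
* The companion logistic OR is undefined under separation and is not a
  substitute for the exact conditional inference.
* Exact conditional tests are conservative at these sample sizes; the null
  rejection rate sits well below the nominal level, and the package makes
  no attempt to de-conservatize (no mid-p option).
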