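---
title: "Mapping direct and indirect genetic effects in a cross-fostered RI panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping direct and indirect genetic effects in a cross-fostered RI panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`igemap` analyses a split-litter cross-fostering design on a recombinant
inbred (RI) panel: each isogenic B6 foster mother rears half a litter of B6
pups and half a litter from one BXD line. Since the mothers and the B6
half-litters are genetically identical across families, genetic mapping of
*their* behaviour can only pick up effects of the social partner's (BXD)
genotype — indirect genetic effects (IGE) — while mapping the BXD
half-litters' own behaviour detects direct effects. This vignette documents
the statistical model, the tunable parameters, the synthetic-data generator,
and the numerical and design choices in the implementation.

# The four-stage model

## Stage 1 — covariate adjustment

Within each stratum (role × trait × observation day), trait values are
modelled by a Gaussian least-squares linear model on six litter/maternal
covariates: maternal bodyweight, average B6 pup weight, B6 litter size,
average BXD pup weight, BXD litter size, and batch. `backward_eliminate()`
removes non-significant terms one at a time: each remaining term is tested
by a partial F-test (`drop1`), the term with the largest p above `alpha`
(default 0.05) is dropped, and the model is refitted, until every remaining
term is significant. Three choices here were genuinely open:

- *One term per iteration*, not batch removal — sequential, stepwise
  elimination is the standard backward procedure and makes the removal
  order auditable.
- *Batch enters and leaves as a whole factor* via the partial F-test.
  Testing its dummy columns individually would make the outcome depend on
  the arbitrary reference level; the factor-level test does not.
- *Ties in p* (possible with degenerate data) are broken by removing the
  term that appears later in the declared covariate order, making the
  procedure deterministic.

Residuals (observed − fitted; observed − grand mean when nothing is
retained) are then averaged per BXD line by `line_means()`. For indirect
traits the averaging key is still the BXD line fostered into the family —
each family hosts exactly one line, so the line mean is well defined for
every role. The covariate model deliberately excludes line identity:
residualization is meant to remove litter-level nuisance variation, not
genetic signal.

## Stage 2 — interval mapping

`qtl_scan()` performs Haley–Knott regression of the line means on the
expected D-allele dosage at every scan position, with

$$\mathrm{LRS} = n \, \ln(\mathrm{RSS}_0 / \mathrm{RSS}_1), \qquad
\mathrm{LOD} = \mathrm{LRS} / 4.61.$$

Between typed markers, the dosage is the conditional probability of the D
allele given the nearest informative flanking markers under a two-state
Markov chain whose step probabilities are the sib-mating-expanded
recombination fractions `expand_rf(haldane_rf(d))` with
$R = 4r/(1+6r)$. With fully inbred lines and line-mean phenotypes this
regression approximation tracks full maximum-likelihood interval mapping
closely; it can diverge near heavy missingness, where dosages shrink toward
1/2 — a documented approximation, acceptable because RI panels are densely
and almost completely genotyped.

Genome-wide significance is assessed by `permutation_null()`: line labels
of the phenotype are permuted (genotypes fixed), the genome-wide maximum
LRS is recorded per permutation, the threshold is the empirical
$(1-\alpha)$ quantile of the maxima, and the p-value of an observed peak is
the add-one estimator $(1 + \#\{\max \ge \mathrm{obs}\})/(n_{perm}+1)$.
Support intervals are 1.5-LOD drops: walking outward from the peak, the
interval ends at the last grid positions whose LOD is still within 1.5 of
the maximum, clamped at chromosome ends, with all endpoints reported in Mb
by linear interpolation of the marker (cM, Mb) pairs.

## Stage 3 — discovery

The scan family is the full design: 3 BXD-offspring traits + 3
B6-offspring traits + 2 maternal traits, each on 3 days — 24 scans of four
behavioural traits, nine direct and fifteen indirect. `bh_select()` applies
Benjamini–Hochberg step-up to the 24 genome-wide permutation p-values at
`q_genome = 0.05`. At the peak marker of each selected scan, the
not-yet-selected *indirect* traits of the same day are then tested by the
point-wise single-marker F-test and selected by Benjamini–Yekutieli step-up
(`by_protected()`, harmonic correction, `q_protected = 0.10`). The BY
candidate set was an open question; the default — all indirect traits at
the selecting scan's day — reflects that the protected test exists to find
*additional indirect* effects at a locus already anchored by a genome-wide
hit.

`co_locate()` groups significant effects on one chromosome whose Mb support
intervals all pairwise overlap (closed intervals, so touching endpoints
count). For one-dimensional intervals pairwise overlap is equivalent to
sharing a common point, so the clique grouping is computed by a sweep over
interval starts that maintains the running intersection — groups split
greedily at the first interval that no longer meets the rest. Groups with
at least one direct member become loci named `SocInt<chr>` (`.2`, `.3`
suffixes if one chromosome hosts several); indirect-only groups are
reported separately and are not loci.

## Stage 4 — validation

For each locus member, `peak_r2()` reports the coefficient of determination
of the line means on the 0/1 genotype at the locus peak marker, and the
allele increasing the trait (D2 for a positive D coefficient, B6
otherwise). The same R² is the "variance explained" figure for both direct
and indirect effects. `trait_correlation()` computes Pearson correlations
between the line means of directly and indirectly affected members at
matching days (across lines — the mapping unit — not across families).
`heritability_anova()` estimates broad-sense heritability as η² =
SS(line)/SS(total) from a one-way ANOVA of *replicate-level* residuals on
line; an ANOVA on line means would be degenerate with one value per line.
Under a global null η² is biased upward with expectation
$(k-1)/(N-1)$ — 31/95 ≈ 0.33 for 32 lines × 3 replicates — which the test
suite verifies by simulation; users should read H² as a broad, upwardly
biased screen, not a variance-component estimate.

# The synthetic-data generator

`sim_scenario()` + `simulate_ri_genotypes()` + `simulate_families()`
emulate the study design so that every stage can be tested against known
truth:

- **Genotypes.** Each line × chromosome is a first-order two-state Markov
  chain over the marker grid (equal founder probabilities at the first
  marker, transition probabilities from the expanded Haldane map function).
  Crossover interference beyond the map expansion is ignored — adequate for
  test data. Heterozygous calls are never generated (fully inbred
  assumption), though the readers accept `H` as missing.
- **Panel and replication.** Defaults: 32 lines, 3 replicate families per
  line, with a 10% dropout probability for each family beyond the first —
  real breeding designs rarely achieve full replication, and the achieved
  counts are rarely published, so dropout is an explicit knob rather than a
  guess; the first family always survives so the panel keeps all lines.
- **Phenotypes.** value = trait baseline + planted direct effect × own
  genotype (BXD rows) + planted indirect effect × fostered-litter genotype
  (B6/mother rows) + covariate slopes + a line-level environmental deviate
  (shared by a line's replicate families, drawn independently per
  role-trait-day) + within-family Gaussian noise. Behavioural scan-sampling
  counts are emulated directly as continuous litter-average values, which
  is also the scale on which mapping operates.
- **Effect scale.** With the defaults (`line_env_sd = 0.29`,
  `noise_sd_within_family = 0.5`, 3 replicates) a planted additive effect
  of 1 trait unit gives an expected line-mean R² of
  $0.25/(0.25 + 0.29^2 + 0.5^2/3) \approx 0.6$ at the causal marker —
  the regime in which the pipeline's recovery guarantees are stated.
- **Covariates.** Maternal bodyweight ~ N(32, 3) g, pup weights ~ N(6, 0.8) g,
  litter sizes uniform on 3–6, batch categorical with 4 levels; slopes are
  small but non-zero so the elimination stage has something real to find.

What the generator does **not** emulate: pre-natal maternal effects (the
fostered pups' prenatal environment differed), non-Gaussian behavioural
count distributions, day-to-day trait autocorrelation, and real BXD linkage
disequilibrium structure. Passing tests therefore demonstrate correctness
of the statistical machinery under the stated generative model, not
robustness to those real-data features.

The default map is synthetic too: 19 autosomes + X (no Y), markers every
10 cM (~160 markers), Mb = 1.9 × cM. A real application would load the
panel's genotype file via `read_geno()` instead.

# Numerical choices

- **LOD divisor** 4.61 by convention (`divisor = "exact"` gives 2·ln 10 ≈
  4.6052 for purists); the two differ by 0.1%.
- **Perfect fits**: RSS₁ = 0 would give infinite LRS; the RSS ratio is
  capped at 10¹² (LRS ≤ n·ln 10¹²) with a warning.
- **Zero-variance traits** scan to an all-zero profile with a warning
  rather than erroring, so batch runs survive degenerate strata.
- **Missing dosages** are handled per position (complete-case), with `n` in
  the LRS formula the per-position case count.
- **Peak ties** are broken toward the first chromosome and smallest Mb.
- **Permutation p** uses the add-one estimator by default so no p is
  exactly zero; `method = "raw"` reproduces the plain proportion.
  Thresholds use `stats::quantile()`'s default (type 7) empirical quantile.
- **Seeding**: every stochastic routine takes an explicit integer seed and
  restores the caller's RNG state (`withr::with_seed`), so identical
  inputs give byte-identical outputs, including written fixtures.

# Problem sizes in the test suite

The simulation-based checks run at deliberately modest sizes chosen to make
their Monte-Carlo error compatible with the asserted tolerances: null
calibration of the genome-wide test at 500 pipeline replicates × 200
permutations; planted-QTL recovery (detection, 1.5-LOD coverage, protected
indirect recovery) at 100 replicates × 200 permutations; FDR step-up
equivalence on 1000 random p-vectors; null heritability at 1000 ANOVA
replicates; elimination retention rates at 200–400 replicates of n = 96.
Production analyses should use `n_perm = 5000`.

# Known limitations

- Single-QTL scans only: no composite interval mapping, multi-QTL models,
  or epistasis.
- The GLM stage assumes Gaussian errors; count-like behavioural traits with
  small denominators may violate this.
- Broad-sense heritability is η², an upwardly biased descriptive measure.
- The borderline-member override mirrors a judgement call (retaining a
  trait that narrowly misses the multiplicity threshold because of a strong
  phenotypic correlation); `igemap` never retains such members silently —
  they appear only if the user adds them to the report explicitly.
- X is scanned like an autosome (valid for homozygous RI panels); Y and
  mitochondria are outside the map.
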