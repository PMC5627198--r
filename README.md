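# igemap

QTL mapping of **direct and indirect genetic effects** in split-litter
cross-fostering designs on recombinant inbred (RI) panels.

## The problem

In a cross-fostered BXD design, each genetically uniform C57BL/6J (B6)
foster mother rears a litter composed of half B6 pups and half pups from one
BXD line. Because mothers and B6 half-litters carry no genetic variation of
their own, any mapping signal in *their* behaviour must be caused by the
genotype of their social partners — the fostered BXD half-litter. `igemap`
maps both effect classes:

- **direct effects** — behaviour of the BXD half-litter regressed on its own
  genotype;
- **indirect genetic effects (IGE)** — behaviour of the B6 siblings and the
  B6 mother regressed on the genotype of the BXD litter mates.

The unit of mapping is the BXD line mean of covariate-adjusted residuals.
For a line-mean trait vector *y* and the expected D-allele dosage *x* at a
scan position, Haley–Knott regression gives the likelihood ratio statistic

LRS = *n* · ln(RSS₀ / RSS₁),  LOD = LRS / 4.61,

with RSS₀ from the intercept-only model. Genome-wide significance comes
from permutations of line labels, support intervals from a 1.5-LOD drop
around the peak, multiplicity control across the 24-scan family (8
role-trait combinations × 3 observation days) from Benjamini–Hochberg
step-up, protected follow-up tests at an established locus from
Benjamini–Yekutieli at q = 0.10, and direct/indirect effects whose support
intervals overlap on one chromosome are merged into a named `SocInt<chr>`
locus. Expected dosage between typed markers uses the two-state Markov
model of the RI genome with sib-mating map expansion R = 4r/(1 + 6r).

Because no real behavioural data ship with the package, a synthetic-data
module simulates the whole design — RI genotypes as a Markov chain over
expanded recombination fractions, cross-fostered families with planted
direct/indirect QTL, litter covariates, line-level environment and
within-family noise — so every stage is testable against known truth.

## Worked example

```r
library(igemap)

map  <- default_map()                       # 19 autosomes + X, 10 cM grid
scen <- sim_scenario(seed = 1)              # 32 lines x 3 replicate families
G    <- simulate_ri_genotypes(map, 32, seed = 1)
fam  <- simulate_families(G, map, scen)     # one planted pleiotropic locus

res <- map_social_qtl(fam, G, map, n_perm = 1000, seed = 101)
res$locus_table[, c("locus", "phenotype", "effect_class", "peak_Mb",
                    "max_LRS", "max_LOD", "genomewide_p", "R2")]
```

```
    locus            phenotype effect_class peak_Mb  max_LRS  max_LOD genomewide_p        R2
1 SocInt4  BXD sibling sucking       direct      76 32.78626 7.111986  0.000999001 0.6410494
2 SocInt4  B6 sibling activity     indirect      76 37.22254 8.074304  0.000999001 0.6875168
3 SocInt4   B6 sibling sucking     indirect      76 34.88218 7.566634  0.000999001 0.6638065
4 SocInt4 B6 maternal suckling     indirect      76 23.05640 5.001388  0.000999001 0.5134972
```

The scenario plants a direct effect on BXD sucking at day 6 and indirect
effects on B6 sibling sucking/activity and maternal suckling at the marker
at 76 Mb on chromosome 4. The pipeline runs all 24 scans, selects the
genome-wide significant ones by BH, adds protected BY hits at the peak
marker, and groups them — here into a single locus `SocInt4` whose members
all cover the true marker. `R2` is the fraction of line-mean variance the
peak marker explains (the planted effects correspond to roughly 0.6);
`genomewide_p` is the add-one permutation p at 1000 permutations.
`res$correlations` shows the positive phenotypic correlations between the
directly and indirectly affected traits, and `res$heritability` the
ANOVA-based broad-sense heritability of each stratum.

## File formats

- **`.geno`** (tab-separated): `@mat B` / `@pat D` / `@unk U` metadata,
  `#` comments, header `Chr Locus cM Mb <line ids...>`, one marker per row
  with calls `B`/`D` (`U`/`H` read as missing). See `read_geno()` /
  `write_geno()`.
- **Phenotype CSV**: one row per family × day × role × trait —
  `family_id, line_id, day, role, trait, value`, plus the covariates
  `maternal_bodyweight, avg_B6_pup_weight, B6_litter_size,
  avg_BXD_pup_weight, BXD_litter_size, batch`. See `read_pheno()`.
- **Locus tables**: TSV + JSON via `write_locus_table()` with columns
  `locus, phenotype, effect_class, day, peak_Mb, CI_Mb_low, CI_Mb_high,
  max_LRS, max_LOD, genomewide_p, allele_increasing, R2, p_type`.

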