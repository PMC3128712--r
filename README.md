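# hlafine

Residue-level fine-mapping of HLA class II case-control associations, with
a desk-scale electrostatics stage for the peptide-binding groove.

HLA disease associations are usually reported per allele, but an allele is
a haplotype of amino acids: the unit that touches the presented peptide is
a residue. `hlafine` takes a four-digit HLA-DRB1 case-control cohort and an
exon-2 protein alignment, assigns every individual two amino acids per
polymorphic position (one per chromosome), and asks which residues carry
the association:

* **Conditional likelihood-ratio scan.** Per residue, disease status is
  regressed on amino-acid copy number (the *allele dosage* model,
  `logit P(case) = b0 + sum_a b_a d_a` with `d_a` in {0,1,2}) or on
  amino-acid pair indicators (the *genotype* model, rare pairs pooled).
  The residue is tested with the LR chi-square
  `2(l_full - l_base)` against a base model holding the residues already
  accepted — single-, two- and three-residue models in turn. Fits use the
  package's own IRLS with explicit separation and collinearity handling.
* **Contingency epidemiology.** Carrier-level and chromosome-level 2x2
  tables, Woolf odds ratios `(ad)/(bc)` with
  `exp(log OR +/- 1.96 sqrt(1/a+1/b+1/c+1/d))` intervals, optional Haldane
  `+0.5`-all-cells correction, chi-square/Fisher tests, Bonferroni
  adjustment.
* **Synthetic cohorts.** A Hardy-Weinberg diplotype simulator with
  logistic residue-driven risk and rejection-sampling ascertainment makes
  every statistical claim testable without patient data.
* **Pocket electrostatics.** A finite-difference linearized
  Poisson-Boltzmann solver (dielectrics 2/80, 0.145 M ions, 1.4 A probe,
  2 A Stern layer, Debye-Hueckel boundaries, two-stage 50%/90% grid
  focusing; PQR in, OpenDX out) classifies binding-pocket patches as
  positive/negative/neutral at the +-5 kT/e surface convention.

## Worked example

```r
library(hlafine)

aln    <- synthetic_drb1_alignment()              # 12 alleles x 30 positions
cohort <- generate_cohort(psc_demo_spec(seed = 1))  # 356 cases / 366 controls
rgm    <- translate_cohort(cohort, aln)
rgm
#> Residue genotype matrix: 722 samples ( 356 cases / 366 controls ), 30 polymorphic positions

head(as.data.frame(residue_scan(rgm))[, c("position", "statistic", "df", "p", "rank")], 3)
#>   position statistic df            p rank
#> 1       37 103.21149  4 2.036770e-21    1
#> 2       16  54.59893  1 1.478161e-13    2
#> 3       25  54.59893  1 1.478161e-13    2
```

The demo simulation plants a per-copy log-odds of ln 3 on asparagine at
residue 37; the single-residue dosage scan ranks that residue first
(LR = 103.2 on 4 df). Residues 16 and 25 partition the synthetic allele
pool identically, hence their tied statistics. Conditioning on the causal
residue removes everything else:

```r
head(as.data.frame(residue_scan(rgm, base_residues = 37))[, c("position", "p")], 2)
#>   position         p
#> 1       12 0.1199293
#> 2       16 0.1199293
```

Single-amino-acid epidemiology on the same cohort:

```r
tab <- carrier_table(rgm, 37, "N")
tab
#> 2x2 table (carrier level) [N37]
#>         exposed unexposed
#> case        272        84
#> control     146       220
woolf_or(tab, "none")
#> OR N37 = 4.879 (95% CI 3.536-6.732) [none correction]
association_test(tab)
#> [1] 2.93e-23
```

An Asn37 carrier in this synthetic cohort has about 4.9-fold odds of
disease — the same order as the published carrier estimates that motivated
the default effect size. Finally, the electrostatics stage labels the sign
of a pocket: a +1 e charge of radius 2 A buried 3 A beneath the patch
yields

```r
pocket <- charge_system(0, 0, 0, charge = 1, radius = 2)
map <- solve_lpb(pocket, pb_params(grid_n = 33, tol = 1e-7),
                 pb_grid(c(0, 0, 0), length = 16, n = 33))
classify_pocket(map, cbind(0, 0, 3))
#> $mean_potential
#> [1] 10.66916
#> $label
#> [1] "positive"
```

Negating the charge flips the label, and the solver is validated against
the screened-Coulomb (Born ion) closed form to within a few percent.

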