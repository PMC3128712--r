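---
title: "Residue-level HLA fine-mapping and pocket electrostatics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residue-level HLA fine-mapping and pocket electrostatics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlafine)
```

## The problem

Classical HLA case-control associations are reported at the allele level
(`DRB1*03:01` versus the rest), but alleles are haplotypes of amino acids:
the biologically active unit is the residue in the peptide-binding groove.
`hlafine` fine-maps a four-digit HLA-DRB1 case-control dataset to amino-acid
resolution in three stages:

1. **Translation.** Each individual carries two alleles; given an exon-2
   protein alignment, every polymorphic position yields an unordered pair of
   amino acids per individual (one per chromosome), and per-amino-acid copy
   numbers (dosages) in {0, 1, 2}.
2. **Conditional likelihood-ratio scan.** For each residue a logistic
   regression of disease status on the residue's amino-acid covariates is
   compared by a likelihood-ratio (LR) chi-square against a base model
   containing only the residues already accepted. Repeating with one, two,
   three conditioning residues gives the familiar stepwise fine-mapping
   scheme, under either an additive *allele dosage* coding or a saturated
   *genotype* (amino-acid pair) coding.
3. **Epidemiology.** For individual amino acids or alleles, 2x2
   carrier-level (individuals with at least one copy) and allele-level
   (chromosome counts) tables give Woolf odds ratios, chi-square/Fisher
   p-values and Bonferroni-adjusted p-values.

A fourth, physically distinct stage asks *why* a residue matters: a
desk-scale finite-difference linearized Poisson-Boltzmann (LPB) solver
computes the electrostatic potential around a point-charge model of the
protein and classifies the sign of a binding-pocket patch.

## Statistical model and its assumptions

With $y_i \in \{0,1\}$ disease status and $d_{ia} \in \{0,1,2\}$ the copy
number of amino acid $a$ at a residue, the dosage model is

$$\mathrm{logit}\, P(y_i = 1) = \beta_0 + \sum_{a \ne \text{ref}} \beta_a d_{ia},$$

i.e. the log-odds contribution of two copies is twice that of one copy. The
genotype model replaces the dosage columns with one indicator per observed
unordered pair, which is saturated at the residue and serves as a check of
the additivity assumption. The residue-level test is the LR statistic
$2(\ell_{\text{full}} - \ell_{\text{base}})$ on as many degrees of freedom
as the residue block adds; p-values come from the chi-square upper tail.
The scan reports raw per-residue p-values (multiple-testing adjustment is
deliberately left to the allele-level epidemiology, where a Bonferroni
factor equal to the number of alleles in the dataset is used).

Key design choices, each of which was genuinely open:

* **Reference category.** LR statistics are invariant to which amino acid
  (or pair) is the reference — this is enforced by a property test — so the
  package picks the most frequent one, deterministically (alphabetical
  tie-break), rather than randomizing.
* **Rare genotype pooling.** In the genotype coding, pairs with fewer than
  `min_count = 2` occurrences in cases *or* in controls are pooled into one
  `rare` category to avoid empty cells. The threshold reads the rule
  literally: "fewer than 2 in cases or controls".
* **Under-filled rare pool.** If the pooled category itself still has fewer
  than `min_count` members in one arm, it is merged into the *most frequent*
  pair category (with a warning) rather than into the reference: merging
  into the reference would make the fitted model depend on the reference
  choice and silently break reference-invariance.
* **Unknown residues.** An allele whose alignment entry is `X` at a
  position excludes its carriers from analyses of that position only, with
  a per-position exclusion count; base and full models of a candidate test
  are always fitted on the identical sample subset, which nested LR tests
  require.
* **Fitting.** Maximum likelihood is obtained by iteratively re-weighted
  least squares with step-halving, declared converged when the relative
  log-likelihood change falls below 1e-10 (at most 100 iterations). A
  rank-deficient design is an error naming the collinear columns; perfect
  separation is flagged (`converged = FALSE`, `separation = TRUE`) and a
  scan records the candidate as failed instead of reporting an inflated
  statistic.

## Contingency statistics

The Woolf odds ratio for a 2x2 table $(a, b, c, d)$ is $(ad)/(bc)$ with the
95% interval $\exp(\log \mathrm{OR} \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$.
Haldane's correction adds 0.5 to *all four* cells before either formula —
always, not only when a cell is zero. Both conventions are exposed because
published tables mix them: allele-frequency tables in this literature use
Haldane throughout (required to reproduce, e.g., an odds ratio of 2.8 where
the uncorrected value would round to 2.9), while in-text carrier ratios are
typically uncorrected. Nothing is inferred from the data; the caller states
the convention.

One documented discrepancy: for the table $(0, 712, 1, 731)$ the
Woolf/Haldane upper confidence limit is about 8.4, whereas the source
literature prints 3.8 for the same table under the same stated formula. The
formula as stated is implemented; the printed interval appears to come from
a different (unstated) procedure and is not chased.

"Chi-square or Fisher where appropriate" is operationalized as Cochran's
rule: Pearson chi-square without continuity correction when all expected
cells are at least 5, otherwise the two-sided Fisher exact test (summing
tables no more probable than the observed one).

## The synthetic cohort generator

Individual-level HLA genotypes are essentially never published, so the
statistical stages are exercised on synthetic cohorts drawn from an
explicit population model:

* diplotypes are two independent draws from a population allele pool
  (Hardy-Weinberg equilibrium, no linkage to other loci, no covariates);
* disease risk is logistic in amino-acid dosage,
  $P(\text{case}) = \mathrm{logis}(\beta_0 + \sum_k \beta_k d_k)$;
* case/control ascertainment is by rejection sampling from the population
  model until both arms are filled (exact, and cheap at desk scale), with
  the retained rows shuffled and the whole procedure reproducible from a
  mandatory seed.

The default demo conditions (`psc_demo_spec()`) are 12 alleles at
control-population frequencies of the magnitude seen in Northern-European
HLA-DRB1 datasets (the five Asn37-encoding alleles at 14.5%, 0.8%, 6.4%,
5.3% and 0.14%), a single causal residue — asparagine at position 37 with a
per-copy log-odds of ln 3 — a baseline log-odds of -2.2 (population
prevalence about 0.17, so rejection sampling fills the arms in a few
thousand draws), and arm sizes of 356 cases and 366 controls. These sizes
and frequencies put the simulations in the same power envelope as the
cohort that motivated the package.

The companion alignment (`synthetic_drb1_alignment()`) is **synthetic**:
real exon-2 sequences are not redistributed. Residues 37 and 86 carry the
published assignments for the five Asn37 alleles (03:01 Asn/Val, 09:01
Asn/Gly, 13:01 Asn/Val, 13:02 Asn/Gly, 14:02 Asn/Gly); the other 28
polymorphic positions use the amino-acid repertoires observed in HLA-DRB1
fine-mapping, with synthetic per-allele assignments. Those assignments were
arranged so that no other residue's partition of the allele pool refines
the Asn/non-Asn split at residue 37, and so that the best linear predictor
of Asn37 dosage from any other single residue has $R^2 \le 0.5$. Real HLA
data are less forgiving — residues within the gene are in near-complete
linkage disequilibrium, and some are perfectly confounded — so passing the
recovery tests here demonstrates correctness of the machinery, not that
real fine-mapping signals are always separable. The generator also omits
haplotype structure beyond DRB1, population stratification, genotyping
error and age/sex effects.

## The electrostatics stage

The LPB equation
$\nabla\!\cdot\!(\varepsilon \nabla \phi) - \bar\kappa^2 \phi = -4\pi C \rho$
is discretized on a uniform cubic grid. Units are fixed: potential in
kT/e, lengths in Angstrom, charges in elementary charges, with
$C = e^2 / (4\pi\varepsilon_0 kT)$ evaluated at the parameter temperature
(default 298.15 K; the protocol the defaults follow specifies pH-7.4-like
conditions but no temperature, so one had to be chosen).

Numerical choices:

* **Geometry.** The solute interior (dielectric 2, no ions) is the union of
  atomic spheres inflated by the 1.4-Angstrom probe; the Stern shell
  extends ion exclusion to radius + 2 Angstrom at solvent dielectric 80;
  beyond that the bulk screening of a 0.145 M 1:1 electrolyte applies.
  The probe-inflated union coincides with a true rolling-probe molecular
  surface only for isolated spheres; re-entrant surfaces of multi-atom
  solutes are not carved out, a documented desk-scale simplification, and
  the analytic benchmarks use single-sphere geometries where the two
  definitions agree.
* **Discretization.** Charges are spread trilinearly to the eight
  surrounding nodes; face dielectrics are harmonic means of the adjacent
  node values (flux continuity); boundary faces carry Debye-Hueckel
  screened-Coulomb superpositions.
* **Solver.** Gauss-Seidel with over-relaxation
  ($\omega = 2/(1+\sin(\pi/n))$ by default), converged when the largest
  node update in a sweep falls below 1e-6 kT/e, capped at 10^4 sweeps;
  non-convergence is an error carrying the update history. Linearity and
  exact antisymmetry under charge negation are enforced by tests.
* **Focusing.** Stage one sizes the grid so the solute spans 50% of the
  edge; stage two re-solves with 90% fill, taking its boundary values by
  trilinear interpolation from the coarse map. Probe/Stern shells may be
  clipped at the fine-grid edge; the fine boundary values come from the
  coarse solution, which was computed with the full geometry.
* **Pocket classification.** The mean interpolated potential over an
  explicit patch of evaluation points is labelled positive/negative beyond
  +-5 kT/e (the conventional surface-coloring cutoff), neutral otherwise.
  Patch geometry must be supplied: no claim is made to reproduce any
  particular published per-allele pocket label, which would require the
  actual modeled structures.

Default grids in the tests and the acceptance script are 65^3 (and 33^3 for
properties like linearity), which resolves the analytic benchmarks to
within a few percent in seconds; the full 251-point, 0.3-Angstrom protocol
grid is supported through `pb_params(grid_n = 251)` but is unnecessary for
the shipped analyses. The 129^3 rung of the refinement ladder isolates
discretization error by imposing exact analytic Dirichlet data, since with
screened-Coulomb boundaries the boundary-condition error (a few percent)
otherwise dominates and masks the h-convergence.

## Problem sizes used by the shipped analyses

The test-suite and acceptance-script simulations use 100 replicates for
causal-recovery and conditional-cleanliness rates, 200 replicates for the
null-uniformity Kolmogorov-Smirnov check, 10^4 diplotype draws for
Hardy-Weinberg goodness of fit, and 65^3 solver grids; these sizes give
stable fractions (recovery rates reproduce to +-0.02 across seeds) while
keeping a full run in tens of seconds.

## Known limitations

* Real allele-to-residue maps contain perfectly confounded residues;
  the scan reports such candidates as failed (collinear) rather than
  attempting to disambiguate them, which only additional data could do.
* The genotype-coding pooling rule can absorb genuinely informative rare
  pairs at small sample sizes; this mirrors the analyzed protocol rather
  than improving on it.
* The electrostatics stage takes point charges and radii as given in the
  PQR input. Protonation/pKa assignment, nonlinear PB, molecular-surface
  triangulation and comparative structure modeling are out of scope.
* Woolf intervals are asymptotic; exact odds-ratio intervals are not
  provided.
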