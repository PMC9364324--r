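---
title: "Predicting metabolite adsorption to nanomaterials: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting metabolite adsorption to nanomaterials: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanosorb)
```

## The problem

Ingested engineered nanomaterials (ENMs) meet the dense chemical milieu of
the gut, where metabolites produced or regulated by the enteric microbiota
can adsorb to the particle surface and change its identity and fate.
`nanosorb` implements a two-stage in-silico pipeline to quantify that
adsorption as `log k`, the base-10 logarithm of an adsorption affinity
constant, for a panel of 19 nanomaterials (13 metal particles, 5 multiwalled
carbon nanotubes, 1 fullerene), plus the statistics needed to compare
materials and to know when the predictions should *not* be trusted.

## Stage 1: the BSAI linear free-energy relationship

The biological surface adsorption index (BSAI) expresses `log k` as a linear
combination of the molecule's five Abraham solvation descriptors,

$$\log k = c + E\,r_e + S\,p_s + A\,a + B\,b + V\,v,$$

where `E` (excess molar refraction), `S` (dipolarity/polarizability), `A`
and `B` (hydrogen-bond acidity and basicity) and `V` (McGowan volume)
characterise the molecule, and the nanodescriptors `[c, r_e, p_s, a, b, v]`
characterise the surface response to the corresponding interaction type
(lone-pair, polarity, H-bond donor/acceptor, hydrophobic). `predict_bsai()`
evaluates this sum exactly; `batch_predict()` fills the full compound-by-ENM
matrix. Whether the underlying affinity is a base-10 or natural logarithm is
not fixed by the relation itself; the package treats it as base-10
throughout, consistent with QSAR convention, and uses the same convention
for the PMF route so the two are comparable.

Measured nanodescriptor values are experimental results that belong to their
authors and are not redistributed here: they are supplied by the user as a
small YAML/JSON registry (`read_nanodescriptors()`). A clearly labelled
synthetic registry ships in `extdata/nanodescriptors_synthetic.yaml` so every
example and test runs self-contained.

BSAI needs experimentally determined Abraham descriptors, which exist for
roughly two thousand small organics. `clean_compound_dataset()` implements
the documented preparation of such a table: SMILES corrections, exclusion of
flagged entries, then collapse of replicate measurements of the same
compound and of descriptor-identical isomers to one random representative
each. The random choice is seed-controlled and the whole operation is
idempotent.

## Stage 2: descriptor-based QSAR models

Because Abraham descriptors cannot be computed from structure alone, a
second, structure-based model is trained per nanomaterial on BSAI
predictions: five molecular descriptors chosen by forward selection from a
large candidate table. The pipeline is:

1. `partition_dataset()` – response-stratified split. The global minimum and
   maximum responders are forced into the training set (no extrapolation),
   the remainder is binned into five response quantiles and each bin is
   split at the training ratio (0.9/0.8/0.7/0.6 supported; 0.8 is the
   packaged default, the ratio that scored best by mean adjusted R² in the
   original analysis).
2. `forward_select()` – at each step the admissible candidate with the
   largest raw R² joins the model; a candidate is admissible only if, after
   joining, every included descriptor has a variance-inflation factor
   (`vif()`) of at most 2. Selection stops at five terms or when no
   admissible candidate improves the fit; the final model is refit by
   ordinary least squares.
3. Validation: the adjusted R² (`adjusted_r2()`) of the held-out set, with
   `n` the validation size and `p` the number of selected terms.

Design choices the procedure leaves open, and what this package does:

* *Ties in R² gain* are broken lexicographically by descriptor name, making
  selection deterministic.
* *Raw vs adjusted R² per step*: raw R² is maximised during selection (with
  a fixed term budget both orderings are usually identical; raw R² is the
  simpler invariant to test).
* *Validation-set adjusted R²* is not uniquely defined for a frozen model;
  the training formula is reused with the validation `n` and `p` = number of
  model terms.

The 19 published equations themselves ship as a frozen JSON registry
(`load_frozen_models()`), each with exactly five terms; evaluating a frozen
model at the all-zero descriptor vector returns its printed intercept, which
the test suite pins for all 19. Descriptor tables are ingested from CSV
(`ingest_descriptor_table()`); a native calculator
(`compute_basic_descriptors()`) covers the eight unambiguous count-type
descriptors (`nAtom`, `nHBDon`, `nRotB`, `nAcid`, `nBase`, `nSmallRings`,
`Fsp3`, `C1SP3`) with documented SMARTS definitions over OpenBabel parsing.
The full vendor descriptor set (autocorrelations, path counts, E-state
fragments) is *not* reimplemented: exact parity with a specific toolkit
version is not verifiable, so those columns are treated as opaque ingested
data.

## Applicability domains

Three constructions, one per question:

* **Insubria graphs** (`insubria_filter()`) for compounds *without* measured
  responses: prediction vs leverage (`leverages()`, the hat-matrix
  diagonal). The critical hat is `h* = 3(N+1)/n` (`critical_hat()`); with
  the five Abraham descriptors and 23 probe compounds this gives the
  reference value 0.78. Modes: both thresholds (leverage and the probe band
  mean ± 3σ), hat-only, none. σ is the sample (n−1) standard deviation.
* **Williams plots** (`williams_flags()`) for training/validation compounds:
  standardized leave-one-out residual (`loo_residuals()`, externally
  studentized) vs leverage; out of domain if |residual| > 3 or `h > h*`.
* **Ordination centroid** (`ordination_centroid_ad()`): NMDS embedding (two
  dimensions, seeded, ≥ 20 restarts) of pairwise Mahalanobis distances;
  in-domain means no farther from the probe centroid than the largest
  probe-to-centroid distance. The reference radius is not prescribed by the
  source procedure; the maximum probe distance is this package's choice and
  makes every probe a member of its own domain.

Boundary conventions are asymmetric on purpose, following the two defining
phrases literally: Insubria retains compounds *smaller than* the critical
hat (`h = h*` is out), Williams excludes compounds *larger than* it
(`h = h*` is in). The three Insubria modes are nested, so the number of
compounds available for model building can only grow as thresholds are
dropped — the property tests check this monotonicity rather than any
dataset-specific count.

## Comparing nanomaterials

`min_shift()` translates a `log k` matrix to non-negative values (subtract
the global minimum), `bray_curtis()` builds the dissimilarity between
materials, and `dbrda_marginal()` tests each nanodescriptor's marginal
contribution by distance-based redundancy analysis: Gower-centre the squared
dissimilarities into `G`, compute each predictor's marginal sum of squares
as the drop in `tr(HG)` when it leaves the full hat matrix, and form
`F = SS_marginal / (SS_residual / (n − p − 1))` — with 19 materials and 5
predictors the denominator df is 13. Negative eigenvalues of `G` are
retained in the totals (the McArdle–Anderson convention); no correction is
applied. Significance comes from freely permuting the rows of the
dissimilarity matrix — raw-row permutation, chosen over residual permutation
because the items are exchangeable under the null — with 999 permutations by
default, so the smallest attainable p-value is 0.001. The implementation is
cross-checked in the tests against an independent constrained-ordination
routine, and its null p-values are verified to be uniform by simulation.

Group contrasts (`kruskal_dunn()`) use the Kruskal–Wallis rank-sum test with
Dunn's tie-corrected pairwise z statistics and Holm step-down adjustment;
`spearman_cor()` wraps the rank correlation used to relate descriptor
families.

## Affinity from molecular dynamics

For molecules outside every QSAR domain, a potential of mean force `w(z)`
from constrained MD yields the same currency:

$$k = \int_0^{c} e^{-\beta w(z)}\,dz, \qquad \beta = 1/(RT),$$

with the material-dependent prefactor omitted, so `k` has units of length
(nm) and is comparable across molecules on one surface. Numerical choices in
`logk_from_pmf()`:

* `R` is the molar gas constant in kJ/(mol·K) because `w` is a per-mole free
  energy; the default temperature is 310 K (the simulation thermostat /
  body temperature).
* The profile is shifted so the bulk plateau mean is zero before
  integration. The omitted prefactor makes any offset a pure multiplicative
  constant, so this standardises comparisons without changing rankings; it
  can be disabled.
* The trapezoid rule is applied to `exp(-βw)` in log-sum-exp form, so wells
  of arbitrary depth cannot overflow; `log10 k` is always finite.
* The cutoff `c` is the onset of the bulk plateau, found by
  `detect_plateau()`: scanning outward from the global minimum, the first
  point where a 5-point forward window fits with |slope| ≤ 2 kJ/(mol·nm)
  and the value is within 1 kJ/mol of the bulk level (mean of the trailing
  window). On discrete grids this necessarily fires within a couple of grid
  steps of the true onset; monotone profiles with no plateau raise an error
  suggesting a longer profile.

`compare_md_qsar()` correlates MD-derived and QSAR-predicted `log k`
(Pearson, with named exclusions applied first — e.g. charged species whose
fixed-charge force-field treatment is suspect).

## Synthetic data: what it emulates and what it does not

All tests run on generated inputs with known ground truth:

* `gen_abraham_compounds()` draws descriptor vectors uniform on ranges
  bracketing typical small-organic values (`E ∈ [−0.5, 3]`, `S ∈ [0, 3]`,
  `A ∈ [0, 2]`, `B ∈ [0, 3]`, `V ∈ [0.3, 3]`), optionally correlated through
  a Gaussian copula. These are plumbing defaults, not a statistical model of
  any measured dataset: passing tests demonstrate the *mechanics* (exact
  linear algebra, selection logic, domain nesting), not predictive accuracy
  on real chemistry.
* `gen_table_from_model()` builds descriptor tables whose response is
  generated exactly by a chosen linear equation, with family-appropriate
  marginals (counts for `n*`/`khs.*`, a fraction for `Fsp3`, continuous
  ranges otherwise) plus independent decoy columns — the instrument for
  coefficient-recovery tests: with noise-free responses, forward selection
  must return the generating descriptors and coefficients to floating-point
  tolerance.
* `gen_pmf()` constructs flat, square-well and smooth (C¹ cosine-squared)
  profiles with closed-form affinities or exactly known plateau onsets.
* `gen_inventory()` produces provenance-tagged inventories of arbitrary
  size for the loader and saturation analysis.

Every generator is a pure function of its configuration (seed included), so
all results in the tests and the acceptance script are reproducible offline.

## The packaged inventory

`enteric_inventory()` returns the curated overview of 170 unique enteric
microbial metabolites in 13 categories plus "other", with per-review
provenance reproducing the saturation curve (137, 161, 170 unique
metabolites after 3, 5, 10 reviews) and the per-category totals. Two
metabolites (acetylcholine, 5-hydroxytryptamine) are stored once with dual
category membership and counted in both categories. Because the published
per-category totals sum to the unique total only if those two records are
counted once, the residual "other" category holds 23 records here rather
than the printed 21 — the reconstruction preserves the unique total, the
saturation curve and every named-category count, and absorbs the two-record
arithmetic slack in "other". The per-metabolite review assignment is
likewise a reconstruction constrained to the published totals, as no
per-record provenance is published; the packaged file is named
`inventory_reconstructed.csv` to make this explicit.

## Problem sizes and runtime

The test suite and the acceptance script are desk-scale by design: 200
compounds for coefficient recovery, 19 × 25 matrices for the ordination
statistics, 200 replicates × 199 permutations for the permutation-test
calibration, and 10⁴-point grids for the integration checks. These sizes are
chosen so every numerical claim is testable in seconds while remaining large
enough that the asymptotic checks (coefficient bias, p-value uniformity,
quadrature convergence) are meaningful.

## Known limitations

* Re-deriving the 19 frozen equations requires the external
  Abraham-descriptor compound dataset and a specific descriptor toolkit;
  the package evaluates and tests the frozen equations but does not claim
  descriptor-level parity with any vendor implementation.
* The BSAI relation does not describe flexible, multi-conformer or heavily
  functionalised molecules (large lipids, polysaccharide MAMPs, bile
  conjugates); that is precisely what the applicability-domain machinery is
  for, and the MD route exists as the fallback.
* MD-side results depend on unpublished PMF curves; the package provides the
  integration and comparison machinery, with synthetic profiles standing in
  for tests.
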