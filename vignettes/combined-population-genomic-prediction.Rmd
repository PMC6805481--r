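---
title: "Combined-population genomic prediction: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combined-population genomic prediction: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, what the synthetic-data generator does
and does not emulate, the numerical choices inside the REML engine, and
the design decisions taken where the problem left genuine latitude.

## The analysis in one paragraph

Small per-farm reference populations limit the accuracy of genomic
prediction in pigs, most severely for low-heritability reproduction
traits. The pipeline studies two remedies jointly: combining reference
populations of one breed from different farms, and replacing chip
genotypes by (imputed) sequence-density genotypes so that causal variants
segregate in the data themselves. The response variable throughout is the
corrected phenotype `y_c` — an EBV-plus-residual construction that removes
fixed-effect noise and avoids double counting of parental information when
the genomic model is trained on descendants of the animals that generated
the phenotypes.

## Corrected phenotypes

Production records are standardised to 100 kg live weight before
modelling: `AGE = age + (100 − w)(age − CF)/w` with CF = 50.775 (males) /
46.415 (females), and `BFT = bft + (100 − w)·bft/(w − CF)` with
CF = −7.277 / −9.440. Both formulas are identities at `w = 100`; weights
outside the 85–130 kg measurement window are computed with a warning
rather than refused.

Pedigree BLUP then supplies EBV and record-level residuals. Reproduction
traits use a repeatability model (herd-year-season fixed effects, additive
genetic, permanent-environment and residual variances); production traits
use a univariate animal model with herd-year-season-sex fixed effects and
a litter effect. Where a bivariate AGE–BFT model could have been fitted,
we deliberately fit two univariate models: the downstream pipeline
consumes per-trait `y_c` only, and a univariate fit avoids assuming an
unknown genetic correlation. Seasons are the windows December–February,
March–May, June–August, September–November; December is rolled into season
1 of the *following* year so a winter is one level. Reliability is
`1 − PEV/σ²_a` with PEV taken from the direct inverse of the MME
coefficient matrix — feasible at the scales this package targets — and
animals under 0.3 are dropped from `y_c`.

One empirical caveat, visible in the test suite: `y_c` beats the raw
phenotype as a proxy for the true breeding value only when the removed
fixed-effect noise outweighs the estimation noise that the correction
itself introduces. With litters of two or three piglets the shrunken
litter estimate inevitably absorbs part of the family genetic signal, so
at herd-year-season effects of SD 0.3 (the generator default) the two are
on par; the property test therefore runs the generator at `hys_sd = 1`,
where correction clearly pays.

## Relationship matrices

The pedigree matrix A comes from the tabular recursion (with inbreeding);
its sparse inverse from Henderson's rules, with inbreeding coefficients
taken from the tabular diagonal, so the two agree to numerical precision
by construction. G is VanRaden method 1, `ZZ′/2Σp(1−p)`, with observed
allele frequencies as the default base; monomorphic markers are dropped
with a message. For the single-step matrix, `G_a = Gβ + α` solves the
two-equation system matching the average diagonal and off-diagonal of G to
those of A₂₂ (A₂₂ is extracted from the full tabular A, not recomputed on
a pruned pedigree, so pedigree depth is honoured), and
`G_w = 0.95 G_a + 0.05 A₂₂`. `H⁻¹` is stored as parts — the sparse A⁻¹
plus the dense genotyped-block correction — and an assembler produces the
dense matrix only for tests and diagnostics.

A fact that shaped the engine: G built with observed frequencies is
*exactly* singular (the centred marker matrix annihilates the ones
vector), so Henderson equations requiring `G⁻¹` cannot be used for GBLUP
directly.

## One REML/BLUP engine, two routes

`reml()` and `solve_blup()` accept arbitrary random terms, each carrying a
covariance `K`, an inverse `Kinv`, or neither (i.i.d.). When every term
has an inverse (pedigree models, ssGBLUP, i.i.d. terms) the engine works
on Henderson's mixed model equations and never forms a dense covariance —
the ssGBLUP contract. When a term brings a dense, possibly singular `K`
(GBLUP, GFBLUP), it works on the phenotypic covariance
`V = Σ σ²_i Z K_i Z′ + σ²_e I`, which stays positive definite for
`σ²_e > 0`. The two routes produce identical likelihoods and solutions on
models where both apply; the test suite checks this against an independent
dense computation of the restricted likelihood.

The maximiser is average-information REML with safeguards:

* damped Newton steps (step halving at 1, 1/2, 1/4, 1/10) accepted only if
  the restricted likelihood does not decrease;
* an active-set reduction: a variance parked at its floor with a downhill
  gradient is frozen and excluded from the AI system (otherwise its row
  poisons the Newton direction);
* EM fallback with extrapolation (step lengthening ×2/×4/×8) — plain EM is
  monotone but crawls geometrically when a component heads to zero;
* a variance floor of `1e-8 · var(y)`; the degenerate GFBLUP case (feature
  set = whole panel) removes the remainder term instead of flooring it;
* convergence when the relative likelihood change is below `1e-8` and
  either the relative parameter change is below `1e-6` or the remaining
  gradient is attributable to components pinned at the floor
  (Karush–Kuhn–Tucker state).

Fixed-effect designs are checked by QR; rank deficiency raises an error
naming the aliased columns rather than silently dropping them, so
confounded herd-year-season levels surface immediately.

## Association scan and genomic features

The scan fits `y_c = 1μ + Zg + xb + e` per marker with `g ~ N(0, G σ²_g)`.
The printed model is a mixed model despite being run on pre-pruned
variants, and that is what we implement; a flag drops the polygenic term
for a pure fixed-effects scan (in which case each test collapses to OLS —
one of the oracle tests). Variance components are estimated once on the
no-marker model and reused across markers (the P3D shortcut); each test is
then a single generalized-least-squares contrast, vectorised over the
panel. Wald p-values use the χ²₁ reference; monomorphic markers are
flagged with `p = 1`. Leave-one-chromosome-out kinship is *not* used;
proximal contamination is accepted and documented here.

GWAS features are the markers at `p ≤ cutoff` (the single SNP, not a
window around it — the window stays configurable); QTL features are
markers inside midpoint-standardised windows of ±100/500/1000 kb with
inclusive, 1-based bounds. Feature sets nest monotonically in the cutoff
and grow monotonically in the half-width; both are asserted as properties.

## Marker QC and imputation metrics

`qc_filter` removes, in order: non-autosomal markers, MAF < 0.01, call
rate < 0.90, then mean-imputes surviving missing dosages. `ld_prune` is a
greedy windowed pruner (default 50 markers, step 5 — the window/step are
not dictated by the method, only the `r² ≥ 0.9` threshold is) that removes
one marker of each high-LD pair. Removing "a random pair" is reproduced by
an optional seeded-random rule; the default deterministic rule removes the
lower-MAF member (ties: the later marker) so reruns are identical. Passes
repeat until no retained within-window pair reaches the threshold, and an
exhaustive checker asserts exactly that.

`imputation_metrics` reports the genotype concordance rate and the squared
Pearson correlation between imputed and true dosages per marker. The
latter is the empirical analogue of Beagle's model-based allelic
R-squared — the model-based quantity needs posterior genotype
probabilities that only the imputation software has, so the label
"analogue" is used deliberately. Markers with truth-MAF below 9.9e-5 are
flagged out of the summaries; bins are 0.01-wide up to MAF 0.05 and
0.05-wide up to 0.5. The error simulator replaces genotypes by
Hardy–Weinberg draws with a per-marker probability that rises as MAF
falls, reproducing the characteristic rise of dosage r² with MAF.

## The synthetic-data generator

Real multi-farm Yorkshire data are not publicly deposited, so the
generator stands in for them, emulating the statistical structure the
analysis relies on:

* **Divergence.** Ancestral frequencies `p₀ ~ U(0.1, 0.9)`; population
  frequencies Beta with mean `p₀` and variance `d·p₀(1−p₀)`
  (Balding–Nichols), so `d` is an Fst knob — Hudson's estimator recovers
  `d` to ±0.03 in the tests.
* **Genome.** Markers placed uniformly on equal-length chromosomes; the
  genetic map is 1 cM/Mb; meiosis draws Poisson crossover counts per
  chromosome. This supports LD-pruning and linkage decay qualitatively but
  is *not* calibrated to real Yorkshire LD (no published farm-level LD
  decay to calibrate against), and there is no mutation or selection.
* **Pedigree.** Non-overlapping generations; per population the number of
  sires is `founders / (dams_per_sire × progeny_per_dam)` so census size
  stays stable; sexes alternate within litters; birth years advance by
  generation with random months so the date-based forward split has
  resolution; herd = population.
* **Panels.** The chip is an evenly spaced (by position) subset of the
  sequence panel, mimicking commercial chip design; a random-subset mode
  exists. QTL are sampled from the sequence panel, so most fall off the
  chip by construction — the mechanism behind the chip-vs-sequence
  contrast.
* **Traits.** Defaults follow pig breeding practice: two repeated
  reproduction traits at h² 0.08/0.09 with a permanent-environment share
  of 0.08 and three parities, and two single-record production traits at
  h² 0.38/0.24 with a litter share of 0.12. True breeding values are
  exactly dosage × effect sums, rescaled so realised `var(TBV)` equals the
  requested h² on a unit phenotypic scale. Herd-year-season effects are
  drawn per level with SD `hys_sd` (default 0.3).

Passing tests on these data show that the *machinery* behaves as the
theory predicts (equivalences, calibration, directional contrasts); they
do not certify accuracy levels on real farm data, whose LD structure,
selection history and fixed-effect landscape the generator deliberately
simplifies.

## Problem sizes

The package targets desk scale by design: dense factorizations up to a few
thousand equations, REML on a thousand animals and a few thousand markers
in seconds. The test suite exercises pedigrees to 500 animals, REML
recovery at n = 1000 / 2000 markers over 20 replicates, scan calibration
at 10 × 2000 null markers, and a 20-replicate two-population prediction
study with ~290 animals each; these sizes are the package's reference
conditions, chosen to make every stochastic check stable under its stated
margin.

## Known limitations

* Univariate models only — no multi-trait REML, no genetic correlations.
* No maternal effects, genetic groups, or inbreeding-depression
  adjustments in the pedigree models.
* No APY or other sparse approximations; ssGBLUP REML at large n would
  need them.
* Imputation itself (phasing/HMM) is out of scope; imputed panels come
  from the error simulator or external tools.
* The GWAS uses a single genomic control-free mixed-model pass; no
  meta-analysis across populations.
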