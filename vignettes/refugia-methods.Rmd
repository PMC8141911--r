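---
title: "Methods: demographic inference and refugium-aware distribution modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: demographic inference and refugium-aware distribution modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refugia)
```

# The scientific problem

Many calcicolous plants of the European Alps occur disjunctly in the Northern
and Southern Limestone Alps, separated by the siliceous central chain that was
heavily glaciated during the Last Glacial Maximum (LGM). Two histories can
produce such a disjunction: survival in separate glacial refugia on both sides
(an old split, by vicariance or by an old founder event), or postglacial
colonization of one side from the other (a recent founder event). `refugia`
implements the quantitative machinery to discriminate these histories from
reduced-representation SNP data and to cross-examine the answer with a
paleoclimate-informed species distribution model (SDM):

1. a structured-coalescent simulator of two-population divergence scenarios
   (the synthetic-data backbone of the package);
2. construction of folded two-dimensional joint site frequency spectra
   (2D-JSFS) from genotypes, with missing-data filtering and hypergeometric
   down-projection;
3. a registry of two-population "island" demographic models, fitted to a
   spectrum by a multi-round perturbation protocol and ranked by AIC and
   Akaike weights;
4. conversion of scaled divergence estimates (tau) to absolute time by
   Monte-Carlo sampling of substitution rates and generation times;
5. per-population diversity descriptors (nucleotide diversity, private
   alleles) and Mann-Whitney comparisons;
6. two-step delta-method downscaling of coarse paleoclimate onto a fine
   climatology, bioclim predictors, and a refugium-augmented pseudo-absence
   GLM.

# Scaling conventions

All demographic quantities follow the diffusion convention: population sizes
`nuA`, `nu1`, `nu2` are relative to an implicit reference size `N_ref`; times
`T`, `T1`, `T2` are in units of `2 N_ref` generations; migration rates `m12`,
`m21` are `2 N_ref` times the per-generation fraction of deme *i* replaced by
migrants from deme *j*. Under this scaling a lineage of deme *i* migrates
(backward in time) at rate `m_ij`, and the scaled mutation rate is
`theta = 4 N_ref mu` per site. Simulated parameters are therefore directly
comparable to fitted ones.

# The coalescent engine

Genealogies are simulated backward in time with an event-driven structured
coalescent (compiled code): within an epoch, each deme contributes a
coalescence process at rate `C(k, 2) / nu(t)` — with `nu(t)` constant or
exponential in time, using closed-form inversion of the integrated hazard —
and each lineage contributes a migration process at its scaled rate. After
the last two-deme epoch all lineages merge into the ancestral deme of size
`nuA`. Mutations follow the infinite-sites model: a Poisson number of
mutations proportional to total branch length, each assigned to a branch with
probability proportional to its length, at a distinct position within the
locus (collisions are redrawn; exceeding the locus length is an error rather
than silent multi-hits). Diploid genotypes pair consecutive haploid
sequences; a haploid single-locus mode is available for organellar-style
data. There is no recombination within loci, no selection, and no
sequencing-error model.

The expected joint SFS of a model is the Monte-Carlo average, over
genealogies, of the branch length subtending each descendant configuration
`(i, j)`. One stream seed is fixed per fit, so repeated evaluations share
common random numbers and the likelihood surface stays relatively smooth in
the parameters. The engine sits behind `engine_settings()` so a
diffusion or moments solver could be substituted; correctness is pinned by
analytic oracles in the test suite (mean pairwise coalescence time 1.0, total
tree length `2 * sum(1/i)`, the neutral `1/i` spectrum, the hypergeometric
split of a panmictic spectrum at a vanishing split time) rather than by
matching any particular external solver.

# The model registry

Eight two-population models span the grid {vicariance, founder} x migration
{none, ancestral asymmetric} x (founder only) island size history {two-epoch,
continuous growth}, plus two "recent founder" variants with the divergence
time bounded below 0.01 scaled time units — recency is purely a timing
constraint. The split divides the ancestral population into founding
fractions `(1 - s) nuA` (mainland, population 1) and `s nuA` (island,
population 2), with `s` capped at 0.5.

The exact event order of the source model set is not recoverable from its
published description, so the registry documents its own semantics precisely
(see `?get_model`): in vicariance models both daughters relax exponentially
from their founding fractions to their current sizes across the whole
post-split span, in the style of published "island" model sets; founder
models hold the mainland at `nu1` and bottleneck the island at `s nuA`
(instantaneous-then-constant in the two-epoch variants, exponential growth in
the growth variants); "ancestral asymmetric migration" acts only during the
older contact epoch `T1`. Five of the eight names are flagged as
reconstructions in `list_models()`. These semantics keep `s` identifiable in
every model and give exact nesting: `vic_anc_asym_mig` with
`m12 = m21 = 0` and `T1 + T2 = T` is `vic_no_mig`.

# Spectrum construction and the likelihood

Genotypes below the depth floor (default 5x) are set missing, sites missing
in more than the tolerated fraction of individuals (default 50%) are dropped,
and an optional one-SNP-per-locus filter thins linked sites. Each remaining
site contributes its hypergeometric projection mass: drawing `m` alleles from
the `n` called alleles of which `d` are derived yields `k` derived with
probability `C(d, k) C(n - d, m - k) / C(n, m)`. Projection is deterministic
(fractional mass, no resampling); mass that lands in the monomorphic corners
is kept there and masked, so conservation is auditable to machine precision.
`choose_projection()` scans candidate sizes and keeps the pair maximizing the
expected number of sites still segregating after projection, breaking ties
toward larger samples. Ancestral states are treated as unknown: all fitting
uses folded spectra, where each cell is combined with its complement, the
redundant half is masked, and cells on the fold line keep the
lexicographically smaller member (self-complementary cells are not doubled).

Model fit uses the Poisson form of the multinomial likelihood: the model
spectrum is scaled by `theta_hat = sum(data) / sum(model)` over unmasked
cells (theta is profiled, reported, and never optimized or counted in `k`),
then `sum(D log lambda - lambda - log D!)` is returned. The likelihood is
invariant to the model's normalization; an all-zero data spectrum yields 0 by
the `theta_hat = 0` convention, and a zero model cell under positive data is
`-Inf` by contract.

# The fitting protocol

`fit_model_multiround()` mirrors the staged search used in SFS pipelines:
round 1 perturbs starting values 3-fold (each coordinate times `2^u`, `u`
uniform on ±fold, clipped to bounds) with 10 replicates, followed by rounds
of 2-, 2- and 1-fold perturbation with 20, 30 and 60 replicates; later rounds
perturb the best parameters found so far. Each replicate is a bounded
derivative-free Nelder-Mead search in log-parameter space (positivity for
free), with an out-of-bounds quadratic penalty. Design choices worth
recording:

* Per-replicate seeds derive deterministically from `(seed, round,
  replicate)`, so a protocol with more replicates extends — never replaces —
  the searches of a smaller one; the best log-likelihood is monotone in the
  protocol and the whole fit is bit-reproducible.
* The evaluation budget is 400 objective evaluations per replicate. A
  tighter budget (200) proved too small for reliable convergence of
  eight-parameter models under Monte-Carlo noise; the budget is a package
  default, adjustable via `maxit`.
* Selection is decoupled from search noise: each replicate's end point (and
  its starting point) is re-scored with 8x the engine replicates on the same
  stream (`refine_factor`), and replicates, round winners and the reported
  log-likelihood — the quantity entering AIC — all use these low-noise
  scores. Without this, a high-dimensional search can "win" on Monte-Carlo
  noise it happened to exploit; scoring the start also guarantees a fit can
  never end below its own starting point.
* The default starting point is the neutral reference (sizes 1, times 0.5,
  migration 1, `s = 0.25`), not a bounds midpoint: in diffusion units the
  null of "nothing happened" is the natural center of the search.

Model ranking follows `AIC = 2k - 2 logL`, `delta_AIC` relative to the best
model, and Akaike weights `exp(-delta/2)` normalized to sum to one. `k`
counts free demographic parameters only.

# Dating

A scaled divergence tau (expected substitutions per site) converts to years
as `t = tau * g / mu`, with the substitution rate `mu` (per site per
generation) and generation time `g` drawn from gamma densities parameterized
by mean and coefficient of variation (shape `1/cv^2`). The defaults encode a
herbaceous-plant rate of 7e-9 with a 10% CV and a fixed generation time of 5,
10 or 20 years. Two conventions deserve note. First, some descriptions write
`tau = 2 mu t`; the package deliberately uses `t = tau / (mu / g)` because
only this convention is internally consistent with dating tables produced
from such tau values — the alternative halves every date. Second, because
`E[1/mu] = (1/mean) * k/(k - 1)` for a gamma with shape `k`, rate uncertainty
shifts the mean date slightly upward relative to the plug-in estimate (about
1% at CV 0.1); this is a property of the sampling scheme, not an error. The
reported 2.5%/97.5% quantiles integrate over rate and generation-time
uncertainty only — no tau posterior is sampled — and are labelled
accordingly; they are narrower than full posterior HPD intervals.

# Diversity descriptors

Per unit: nucleotide diversity uses the unbiased per-site estimator
`n/(n - 1) * 2p(1 - p)` on called alleles, skipping sites with fewer than two
called alleles in that unit; expected heterozygosity omits the correction;
the percentage of polymorphic sites counts `0 < p < 1`; `sites_recovered`
counts sites with at least one called genotype in the unit (a definition the
source pipelines leave open); private alleles are alleles (REF or ALT)
observed in that unit and in no other unit of the analysis — privacy is
relative to the analysis, not to a global panel. The Mann-Whitney comparison
uses midranks, exact enumeration of group assignments for combined sizes up
to 12, and the tie-corrected normal approximation otherwise.

# Paleoclimate downscaling and the SDM

The delta method transfers coarse climate anomalies onto a fine reference
climatology: differences for temperature, ratios for precipitation
(zero-reference cells get a flagged "no change"; negative products clamp to
zero with a flag). Because paleoclimate simulations and fine observational
climatologies rarely share a reference period, the chain runs in two steps —
paleo anomalies (historic window vs. an early reference window) interpolated
onto a mid-resolution observational series, then anomalies of that modified
series (vs. the fine climatology's base period) interpolated onto the fine
grid. Interpolation is an exact thin-plate spline (`r^2 log r` kernel plus
affine part) through the non-missing coarse cell centers; it reproduces node
values and affine fields exactly, which gives the key invariant that a
stationary climate passes through the whole chain unchanged. Deltas are
computed and interpolated per month; bioclim variables are derived only after
downscaling: bio1 (annual mean temperature), bio4 (100 x SD of monthly mean
temperatures), bio12 (annual precipitation), bio15 (100 x CV of monthly
precipitation). Sample SD (denominator `n - 1`) is used for bio4/bio15
following the common bioclim convention, population SD for topographic
roughness (an aggregation, not an estimate). Collinearity is screened by
pairwise Pearson `|r| > 0.7` with constant layers flagged as undefined.

The SDM is a binomial GLM with intercept plus linear and quadratic terms for
each predictor, fitted by IRLS to tolerance 1e-8 on internally standardized
predictors. Pseudo-absences are uniform draws from the domain minus exclusion
masks. When a model trained on the current range is too narrow to survive a
cold period, `augment_with_refugia()` adds, per refugial area, the
historic-climate cell with the highest predicted probability as a presence
(carrying its historic climate), regenerates pseudo-absences half from
historic and half from current climate (excluding refugia, glaciated areas
and the current range), and refits. Refugial polygons and glacier masks are
inputs, not inferences. Complete separation is detected (zero residual
deviance or the IRLS warning) and flagged rather than hidden. Grid I/O uses
a plain-text matrix format (header plus rows, `-9999` as missing); derived
layers can be resampled by nearest neighbor simply by evaluating on the
target grid.

# What the synthetic data do and do not emulate

The generator reproduces the features the downstream statistics actually
consume: two-deme biallelic SNPs under the divergence scenarios, per-genotype
depths, independent missingness at a controlled rate, and locus structure for
linkage thinning. It does not emulate RAD library artifacts (allele dropout
correlated with divergence, paralog collapse, depth-dependent genotyping
error), selection, or within-locus recombination. Passing tests therefore
certify the estimators and the inference machinery, not robustness to every
RAD pathology; absolute diversity values of any real data set are not
reproduced by design.

# Problem sizes and numerical choices

The test-suite simulations run at desk scale, chosen as the smallest sizes
at which the checked contrasts are decisively resolved: coalescent oracles at
1e5 genealogies; spectra for model selection at samples of 8+8 haploids and
1e4 SNPs; the model-recovery experiment at 20 seeded replicates of a
scaled-down two-round protocol (folds 2 and 1, 5 and 10 replicates, 1000
engine genealogies per evaluation with 8x refinement); one-parameter
recovery on a 20-haploid sample with a recent size change (`T = 0.05`), where
the spectrum is sharply informative about `nu`; dating at 1e6 gamma draws;
SDM recovery at n = 5000. Engine defaults (2e4 genealogies for standalone
expected spectra, 2e3 during iterated fitting) balance Monte-Carlo noise
against cost; raise them for final parameter estimates. Tolerances follow
the quantity: exact identities to 1e-12 (projection mass, Akaike weight
normalization), interpolation exactness to 1e-8, Monte-Carlo quantities to
three standard errors of their own batch variance.

# Known limitations

* The expected-SFS engine is stochastic; likelihood surfaces carry
  Monte-Carlo noise, and very small expected masses in large spectra need
  more engine replicates than the defaults.
* `s` in vicariance models is identified only through the founding-fraction
  size trajectory; with nearly constant sizes its likelihood contribution is
  weak, so fitted `s` values should be interpreted cautiously.
* Dating quantiles understate full posterior uncertainty (no tau posterior).
* No bootstrap or Godambe uncertainty for fitted demographic parameters, and
  no conversion of fitted scaled parameters to absolute units.
* The SDM works on whatever grid and masks it is given; it performs no
  geographic projection, and GeoTIFF is not among the supported formats —
  use the plain-text grid exchange format.
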