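# refugia

Demographic inference and glacial-refugium distribution modeling for
disjunctly distributed alpine plants.

Mountain plants restricted to calcareous bedrock often occur on both sides of
the heavily glaciated central Alps. Did such species survive the Last Glacial
Maximum in refugia on *both* peripheries, or did one side get recolonized
after the ice retreated? `refugia` provides the full quantitative toolchain
used to answer that question from RADseq-style SNP data and gridded climate:

* **Coalescent simulation** of two-population divergence scenarios
  (vicariance, old founder event, recent founder event) under a structured
  coalescent with migration epochs, exponential size trajectories, and
  infinite-sites mutation — the package's own synthetic-data generator, with
  VCF export and RADseq-style missingness/depth injection.
* **Joint site frequency spectra**: folded 2D-JSFS construction from
  genotypes with depth and missing-data filters, deterministic hypergeometric
  down-projection (`C(d,k) C(n-d,m-k) / C(n,m)` mass redistribution), and the
  Poisson form of the multinomial likelihood with the scaling parameter
  `theta` profiled out (`theta_hat = sum(D)/sum(M)`).
* **Model selection**: a registry of eight two-population "island" models
  (`vic_no_mig`, `vic_anc_asym_mig`, founder and recent-founder variants),
  a Monte-Carlo expected-SFS engine with common random numbers, the
  multi-round perturbation fitting protocol (3-, 2-, 2-, 1-fold; 10/20/30/60
  replicates), and ranking by `AIC = 2k - 2 logL`, `delta_AIC` and Akaike
  weights `exp(-delta/2) / sum exp(-delta/2)`.
* **Dating**: conversion of a scaled divergence `tau` (expected substitutions
  per site) to absolute time via `t = tau * g / mu`, sampling `mu` and `g`
  from gamma densities (mean 7e-9, CV 10% by default).
* **Diversity descriptors**: per-population nucleotide diversity `pi`
  (unbiased `n/(n-1)` correction), expected heterozygosity, percent
  polymorphic sites, private alleles, and Mann-Whitney comparisons with exact
  tie-aware p-values at small samples.
* **Paleo-SDM**: two-step delta-method downscaling (temperature differences,
  precipitation ratios, exact thin-plate-spline interpolation), bioclim
  predictors (bio1, bio4, bio12, bio15) plus topographic roughness, a
  collinearity screen, and a pseudo-absence binomial GLM with quadratic
  terms that can be augmented with refugial presences and refitted.

## Worked example

Simulate a vicariance history, build the folded joint spectrum, fit two
competing models and rank them:

```r
library(refugia)

cfg <- scenario_config("vicariance",
                       params = list(nuA = 1, nu1 = 3, nu2 = 3,
                                     T1 = 0.5, T2 = 0.4, s = 0.5,
                                     m12 = 0.5, m21 = 5),
                       n1 = 16, n2 = 16, n_loci = 2000,
                       theta_per_site = 0.004, seed = 42)
gm <- inject_missingness(simulate_demography(cfg), 0.2, seed = 1)
gm
#> <genotype_matrix> 16 individuals x 6288 sites; populations: pop1 (8), pop2 (8); 19.9% missing
sfs <- jsfs_from_genotypes(gm, c("pop1", "pop2"),
                           filters = sfs_filter_config(max_missing_fraction = 0.5,
                                                       min_depth = 5),
                           projection = "auto")
sfs
#> <joint_sfs> n1 = 10, n2 = 8, folded; 4496.3 units of mass in 49 unmasked cells
fits <- lapply(c("vic_anc_asym_mig", "vic_no_mig"), function(m)
  fit_model_multiround(sfs, get_model(m),
                       protocol = list(folds = c(2, 1), replicates = c(5, 10)),
                       seed = 7, engine = engine_settings(1000), maxit = 350))
model_selection_table(fits)
#>              model k log_likelihood      AIC delta_AIC akaike_weight theta_hat
#> 1 vic_anc_asym_mig 8      -149.9457 315.8915    0.0000      0.998828  495.3584
#> 2       vic_no_mig 5      -159.6940 329.3879   13.4964      0.001172 1054.5999
```

The generating model (vicariance with ancient asymmetric migration) wins
decisively: `delta_AIC` ≈ 13.5 for the no-migration alternative, Akaike
weight ≈ 0.999 for the truth. The down-projection was chosen automatically
(10 and 8 haploid alleles) to maximize the polymorphism retained under 20%
missing data.

Date a scaled divergence of `6.2e-4` substitutions per site at a 5-year
generation time:

```r
tau_to_absolute_time(6.2e-4,
                     calibration_config(mu_mean = 7e-9, mu_cv = 0.10,
                                        generation_time = 5,
                                        n_draws = 1e6, seed = 7))
#> <time_estimate> tau = 0.00062, g = 5 y: mean 0.447 mya (quantiles 0.367-0.544; rate/generation uncertainty only)
```

A mid-Pleistocene split — far older than the LGM, i.e. evidence against
postglacial colonization.

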