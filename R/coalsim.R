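#' Scenario configuration for the synthetic-data generator
#'
#' Bundles a divergence scenario, its demographic parameters and the sampling
#' design for coalescent simulation of two-deme SNP data.  The three scenario
#' names map onto registered demographic models: `vicariance` uses
#' `vic_anc_asym_mig` when migration rates are supplied and `vic_no_mig`
#' otherwise; `old_founder` likewise uses `founder_anc_asym_two_epoch` or
#' `founder_nomig_two_epoch`; `recent_founder` uses
#' `recent_founder_nomig_growth` and requires the divergence time to lie
#' below `recent_threshold` (scaled time; the scenarios differ only in
#' timing).
#'
#' @param scenario one of `"vicariance"`, `"old_founder"`,
#'   `"recent_founder"`.
#' @param params named list of demographic parameters (diffusion scaling, see
#'   [get_model()]).
#' @param n1,n2 haploid sample sizes per deme (must be even when diploid
#'   genotypes are requested).
#' @param n_loci number of independent, non-recombining loci.
#' @param locus_length sites per locus.
#' @param theta_per_site scaled mutation rate `4 N_ref mu` per site.
#' @param recent_threshold upper bound on scaled divergence time for the
#'   recent-founder scenario.
#' @param seed integer seed.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(scenario = c("vicariance", "old_founder",
                                         "recent_founder"),
                            params, n1 = 12, n2 = 12, n_loci = 500,
                            locus_length = 100, theta_per_site = 0.004,
                            recent_threshold = 0.01, seed = 1) {
  scenario <- match.arg(scenario)
  stopifnot(n1 >= 1 || n2 >= 1, n_loci >= 1, locus_length >= 1)
  if (theta_per_site < 0) stop("theta_per_site must be >= 0", call. = FALSE)
  params <- as.list(params)
  has_mig <- all(c("m12", "m21") %in% names(params)) &&
    any(unlist(params[c("m12", "m21")]) > 0)
  model_name <- switch(scenario,
    vicariance = if (has_mig) "vic_anc_asym_mig" else "vic_no_mig",
    old_founder = if (has_mig) "founder_anc_asym_two_epoch" else "founder_nomig_two_epoch",
    recent_founder = "recent_founder_nomig_growth")
  if (scenario == "recent_founder") {
    if (is.null(params$T) || params$T >= recent_threshold)
      stop(sprintf("recent_founder requires T < %g (scaled time)",
                   recent_threshold), call. = FALSE)
  }
  structure(
    list(scenario = scenario, model_name = model_name, params = params,
         n1 = as.integer(n1), n2 = as.integer(n2),
         n_loci = as.integer(n_loci), locus_length = as.integer(locus_length),
         theta_per_site = theta_per_site, seed = as.numeric(seed)),
    class = "scenario_config"
  )
}

config_schedule <- function(config) {
  model <- get_model(config$model_name)
  p <- check_params(model, config$params)
  model$builder(p)
}

#' Simulate diploid SNP genotypes under a divergence scenario
#'
#' Runs the structured coalescent for `n_loci` independent loci, drops
#' infinite-sites mutations on the genealogies (`theta_locus =
#' theta_per_site * locus_length`), and pairs consecutive haploid sequences
#' into diploid individuals.  Output is fully reproducible from the
#' configuration seed.
#'
#' @param config a [scenario_config()].
#' @param haploid return one individual per haploid sequence instead of
#'   pairing (single-locus organellar-style data).
#' @return A [genotype_matrix()] containing every polymorphic site.
#' @export
simulate_demography <- function(config, haploid = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  if (!haploid && (config$n1 %% 2L != 0L || config$n2 %% 2L != 0L))
    stop("diploid output requires even haploid sample sizes per deme",
         call. = FALSE)
  sch <- config_schedule(config)
  theta_locus <- config$theta_per_site * config$locus_length
  loci <- cpp_sim_loci(config$n1, config$n2, sch$len, sch$s1, sch$r1,
                       sch$s2, sch$r2, sch$m12, sch$m21, sch$nuA,
                       config$n_loci, theta_locus, config$locus_length,
                       derive_seed(config$seed, 11))
  n_hap <- config$n1 + config$n2
  hap_pop <- rep(c("pop1", "pop2"), c(config$n1, config$n2))

  haps <- list(); locus_id <- list(); pos <- list()
  for (l in seq_along(loci)) {
    h <- loci[[l]]$hap
    if (nrow(h) == 0L) next
    ord <- order(loci[[l]]$pos)
    haps[[length(haps) + 1L]] <- h[ord, , drop = FALSE]
    locus_id[[length(locus_id) + 1L]] <- rep(sprintf("locus%05d", l), nrow(h))
    pos[[length(pos) + 1L]] <- sort(loci[[l]]$pos)
  }
  if (length(haps) == 0L) {
    hap_mat <- matrix(integer(0), nrow = 0L, ncol = n_hap)
    sites <- tibble::tibble(locus = character(0), pos = integer(0))
  } else {
    hap_mat <- do.call(rbind, haps)
    sites <- tibble::tibble(locus = unlist(locus_id), pos = unlist(pos))
  }

  if (haploid) {
    gt <- t(hap_mat)  # individuals x sites, 0/1
    genotype_matrix(gt, pop = hap_pop, sites = sites)
  } else {
    odd <- seq(1L, n_hap, by = 2L)
    gt <- t(hap_mat[, odd, drop = FALSE] + hap_mat[, odd + 1L, drop = FALSE])
    genotype_matrix(gt, pop = hap_pop[odd], sites = sites)
  }
}

#' Simulate a joint site frequency spectrum directly
#'
#' Accumulates the unfolded joint SFS over `n_reps` replicate genealogies:
#' branch lengths subtending each descendant configuration are summed and SNP
#' counts are drawn as Poisson with mean `theta_locus / 2` times the
#' accumulated length per cell (the infinite-sites expectation over
#' independent loci).  With `expected = TRUE` the Poisson draw is skipped and
#' the branch-length expectation itself is returned (averaged, not
#' accumulated).
#'
#' @param config a [scenario_config()]; `n_reps` genealogies are simulated at
#'   the configured sample sizes.
#' @param n_reps number of replicate genealogies (defaults to the
#'   configuration's locus count).
#' @param expected return the expectation instead of a Poisson realization.
#' @return An unfolded `joint_sfs` with zero mass in the corner cells.
#' @export
simulate_joint_sfs <- function(config, n_reps = config$n_loci,
                               expected = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  sch <- config_schedule(config)
  mean_len <- cpp_branch_jsfs(config$n1, config$n2, sch$len, sch$s1, sch$r1,
                              sch$s2, sch$r2, sch$m12, sch$m21, sch$nuA,
                              as.integer(n_reps), derive_seed(config$seed, 23))
  theta_locus <- config$theta_per_site * config$locus_length
  lam <- theta_locus / 2 * mean_len
  if (expected) return(jsfs(lam, folded = FALSE))
  total <- lam * n_reps
  withr_seed(derive_seed(config$seed, 29), {
    counts <- matrix(rpois(length(total), total), nrow = nrow(total))
  })
  jsfs(counts, folded = FALSE)
}

# evaluate `code` under a temporary R RNG seed, restoring the caller's state
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  code
}

#' Inject RADseq-style missingness and sequencing depth
#'
#' Sets each genotype independently to missing with probability
#' `missing_rate` and draws per-genotype depths from a negative-binomial
#' depth model (missing genotypes get depth 0 with probability
#' `depth_model$p_zero`, otherwise a fresh draw), so the depth and
#' missing-fraction filters of the SFS builder are exercisable on synthetic
#' data.
#'
#' @param gm a [genotype_matrix()].
#' @param missing_rate per-genotype missing probability in `[0, 1)`.
#' @param depth_model list with `mean` (mean depth), `size`
#'   (negative-binomial dispersion; `Inf` gives Poisson) and `p_zero`
#'   (probability that a missing call has depth 0).
#' @param seed integer seed.
#' @return A new `genotype_matrix`; population labels unchanged.
#' @export
inject_missingness <- function(gm, missing_rate,
                               depth_model = list(mean = 20, size = 5,
                                                  p_zero = 0.5),
                               seed = 1) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  if (missing_rate == 0) return(gm)
  gt <- gm$gt; depth <- gm$depth
  withr_seed(derive_seed(seed, 31), {
    miss <- matrix(runif(length(gt)) < missing_rate, nrow = nrow(gt))
    size <- depth_model$size %||% Inf
    d <- if (is.finite(size))
      stats::rnbinom(length(gt), size = size, mu = depth_model$mean)
    else rpois(length(gt), depth_model$mean)
    d <- matrix(pmax(1L, as.integer(d)), nrow = nrow(gt))
    zero <- matrix(runif(length(gt)) < (depth_model$p_zero %||% 0.5),
                   nrow = nrow(gt))
    d[miss & zero] <- 0L
  })
  gt[miss] <- NA_integer_
  genotype_matrix(gt, pop = gm$pop, depth = d, sites = gm$sites, ind = gm$ind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
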