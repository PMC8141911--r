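#' Registry of two-population island demographic models
#'
#' Eight divergence models for a pair of populations split from an ancestral
#' population of relative size `nuA`, built from the grid scenario
#' \{vicariance, founder\} x migration \{none, ancestral asymmetric\} x
#' (founder only) size history \{two-epoch expansion-then-constant,
#' continuous exponential growth\}, plus two "recent founder" variants whose
#' divergence time is bounded small.  Three names follow the published
#' island-model nomenclature (`vic_no_mig`, `vic_anc_asym_mig`,
#' `founder_anc_asym_two_epoch`); the remaining five are reconstructions in
#' the same style and are flagged as such in the registry listing.
#'
#' All quantities follow the diffusion scaling: population sizes `nuA`,
#' `nu1`, `nu2` are relative to the reference size `N_ref`, times `T`, `T1`,
#' `T2` are in units of `2 N_ref` generations, and migration rates `m12`,
#' `m21` are `2 N_ref` times the per-generation fraction of deme `i` replaced
#' by migrants from deme `j`.  The split divides the ancestral population
#' into founding fractions `(1 - s) nuA` (population 1, the mainland) and
#' `s nuA` (population 2, the island), with `0 < s <= 0.5`.
#'
#' Model semantics (backward in time from the present):
#' * `vic_no_mig` (`nuA, nu1, nu2, T, s`): both daughters follow an
#'   exponential size trajectory from their founding fraction at the split to
#'   their current size; no migration.
#' * `vic_anc_asym_mig` (`nuA, nu1, nu2, T1, T2, s, m12, m21`): same size
#'   trajectories over the total span `T1 + T2`; asymmetric migration during
#'   the older contact epoch `T1`, isolation during the recent epoch `T2`.
#' * `founder_nomig_two_epoch` (`nuA, nu1, nu2, T1, T2, s`): mainland
#'   constant at `nu1`; island at its founding size `s nuA` for `T1`, then
#'   instantaneously at `nu2` for the recent epoch `T2`; no migration.
#' * `founder_anc_asym_two_epoch` (+ `m12, m21`): as above with migration
#'   during the older epoch only.
#' * `founder_nomig_growth` (`nuA, nu1, nu2, T, s`): mainland constant at
#'   `nu1`; island grows exponentially from `s nuA` to `nu2` over `T`.
#' * `founder_anc_asym_growth` (+ `T1, T2, m12, m21`): growth over the total
#'   span; migration during the older epoch only.
#' * `recent_founder_nomig_growth`, `recent_founder_nomig_two_epoch`: the
#'   founder models with divergence time bounded below 0.01 (scaled time),
#'   encoding a post-glacial colonization.
#'
#' @param name model identifier.
#' @return `get_model()` returns a `demog_model` (name, ordered free
#'   parameters, bounds, schedule builder); `list_models()` returns a tibble
#'   describing the registry.
#' @examples
#' get_model("vic_no_mig")$free_params
#' @export
get_model <- function(name) {
  reg <- model_registry()
  if (!name %in% names(reg))
    stop(sprintf("unknown model '%s'; registered models: %s", name,
                 paste(names(reg), collapse = ", ")), call. = FALSE)
  reg[[name]]
}

#' @rdname get_model
#' @export
list_models <- function() {
  reg <- model_registry()
  tibble::tibble(
    model = names(reg),
    k = vapply(reg, function(m) length(m$free_params), integer(1)),
    free_params = vapply(reg, function(m) paste(m$free_params, collapse = ", "),
                         character(1)),
    reconstructed = vapply(reg, function(m) m$reconstructed, logical(1))
  )
}

new_demog_model <- function(name, free_params, bounds, builder,
                            reconstructed = FALSE) {
  stopifnot(all(names(bounds) == free_params))
  structure(
    list(name = name, free_params = free_params, bounds = bounds,
         builder = builder, k = length(free_params),
         reconstructed = reconstructed),
    class = "demog_model"
  )
}

#' @export
print.demog_model <- function(x, ...) {
  cat(sprintf("<demog_model> %s (k = %d): %s\n", x$name, x$k,
              paste(x$free_params, collapse = ", ")))
  invisible(x)
}

# default bounds, diffusion units
.b_nu <- c(1e-3, 100)
.b_T <- c(1e-3, 10)
.b_Trec <- c(1e-4, 0.01)
.b_Trec2 <- c(5e-5, 0.005)
.b_s <- c(0.01, 0.5)
.b_m <- c(0, 20)  # zero allowed (nested no-migration case); fits use a
                  # positive floor for the log transform

# A schedule is the epoch table the coalescent engine consumes: vectors
# ordered from the present backward, plus the ancestral size.
schedule <- function(len, s1, r1, s2, r2, m12, m21, nuA) {
  list(len = len, s1 = s1, r1 = r1, s2 = s2, r2 = r2,
       m12 = m12, m21 = m21, nuA = nuA)
}

# Exponential-trajectory rate: size equals `cur` now and `anc` at time span
# `TT` in the past, nu(t) = cur * exp(rate * t).
traj_rate <- function(cur, anc, TT) log(anc / cur) / TT

model_registry <- function() {
  reg <- list()

  reg$vic_no_mig <- new_demog_model(
    "vic_no_mig",
    c("nuA", "nu1", "nu2", "T", "s"),
    list(nuA = .b_nu, nu1 = .b_nu, nu2 = .b_nu, T = .b_T, s = .b_s),
    function(p) {
      r1 <- traj_rate(p$nu1, (1 - p$s) * p$nuA, p$T)
      r2 <- traj_rate(p$nu2, p$s * p$nuA, p$T)
      schedule(p$T, p$nu1, r1, p$nu2, r2, 0, 0, p$nuA)
    })

  reg$vic_anc_asym_mig <- new_demog_model(
    "vic_anc_asym_mig",
    c("nuA", "nu1", "nu2", "T1", "T2", "s", "m12", "m21"),
    list(nuA = .b_nu, nu1 = .b_nu, nu2 = .b_nu, T1 = .b_T, T2 = .b_T,
         s = .b_s, m12 = .b_m, m21 = .b_m),
    function(p) {
      TT <- p$T1 + p$T2
      r1 <- traj_rate(p$nu1, (1 - p$s) * p$nuA, TT)
      r2 <- traj_rate(p$nu2, p$s * p$nuA, TT)
      schedule(c(p$T2, p$T1),
               c(p$nu1, p$nu1 * exp(r1 * p$T2)), c(r1, r1),
               c(p$nu2, p$nu2 * exp(r2 * p$T2)), c(r2, r2),
               c(0, p$m12), c(0, p$m21), p$nuA)
    })

  founder_two_epoch_builder <- function(with_mig) {
    function(p) {
      m12 <- if (with_mig) p$m12 else 0
      m21 <- if (with_mig) p$m21 else 0
      schedule(c(p$T2, p$T1),
               c(p$nu1, p$nu1), c(0, 0),
               c(p$nu2, p$s * p$nuA), c(0, 0),
               c(0, m12), c(0, m21), p$nuA)
    }
  }

  reg$founder_nomig_two_epoch <- new_demog_model(
    "founder_nomig_two_epoch",
    c("nuA", "nu1", "nu2", "T1", "T2", "s"),
    list(nuA = .b_nu, nu1 = .b_nu, nu2 = .b_nu, T1 = .b_T, T2 = .b_T,
         s = .b_s),
    founder_two_epoch_builder(FALSE), reconstructed = TRUE)

  reg$founder_anc_asym_two_epoch <- new_demog_model(
    "founder_anc_asym_two_epoch",
    c("nuA", "nu1", "nu2", "T1", "T2", "s", "m12", "m21"),
    list(nuA = .b_nu, nu1 = .b_nu, nu2 = .b_nu, T1 = .b_T, T2 = .b_T,
         s = .b_s, m12 = .b_m, m21 = .b_m),
    founder_two_epoch_builder(TRUE))

  founder_growth_builder <- function(with_mig) {
    function(p) {
      if (with_mig) {
        TT <- p$T1 + p$T2
        r2 <- traj_rate(p$nu2, p$s * p$nuA, TT)
        schedule(c(p$T2, p$T1),
                 c(p$nu1, p$nu1), c(0, 0),
                 c(p$nu2, p$nu2 * exp(r2 * p$T2)), c(r2, r2),
                 c(0, p$m12), c(0, p$m21), p$nuA)
      } else {
        r2 <- traj_rate(p$nu2, p$s * p$nuA, p$T)
        schedule(p$T, p$nu1, 0, p$nu2, r2, 0, 0, p$nuA)
      }
    }
  }

  reg$founder_nomig_growth <- new_demog_model(
    "founder_nomig_growth",
    c("nuA", "nu1", "nu2", "T", "s"),
    list(nuA = .b_nu, nu1 = .b_nu, nu2 = .b_nu, T = .b_T, s = .b_s),
    founder_growth_builder(FALSE), reconstructed = TRUE)

  reg$founder_anc_asym_growth <- new_demog_model(
    "founder_anc_asym_growth",
    c("nuA", "nu1", "nu2", "T1", "T2", "s", "m12", "m21"),
    list(nuA = .b_nu, nu1 = .b_nu, nu2 = .b_nu, T1 = .b_T, T2 = .b_T,
         s = .b_s, m12 = .b_m, m21 = .b_m),
    founder_growth_builder(TRUE), reconstructed = TRUE)

  reg$recent_founder_nomig_growth <- new_demog_model(
    "recent_founder_nomig_growth",
    c("nuA", "nu1", "nu2", "T", "s"),
    list(nuA = .b_nu, nu1 = .b_nu, nu2 = .b_nu, T = .b_Trec, s = .b_s),
    founder_growth_builder(FALSE), reconstructed = TRUE)

  reg$recent_founder_nomig_two_epoch <- new_demog_model(
    "recent_founder_nomig_two_epoch",
    c("nuA", "nu1", "nu2", "T1", "T2", "s"),
    list(nuA = .b_nu, nu1 = .b_nu, nu2 = .b_nu, T1 = .b_Trec2,
         T2 = .b_Trec2, s = .b_s),
    founder_two_epoch_builder(FALSE), reconstructed = TRUE)

  reg
}

#' Single-population size-change model
#'
#' An auxiliary one-parameter model (current relative size `nu` since a fixed
#' time `T` in the past, ancestral size 1) used for parameter-recovery
#' checks; it is deliberately not part of the two-population registry.
#'
#' @param T fixed epoch duration in units of `2 N_ref` generations; the
#'   default places a recent size change, where the spectrum is most
#'   informative about `nu`.
#' @return A `demog_model` with single free parameter `nu`.
#' @export
onepop_size_change_model <- function(T = 0.05) {
  force(T)
  new_demog_model(
    "onepop_size_change",
    "nu",
    list(nu = .b_nu),
    function(p) schedule(T, p$nu, 0, 1, 0, 0, 0, 1),
    reconstructed = TRUE)
}

#' Engine settings for the expected-SFS computation
#'
#' The expected spectrum is computed by Monte-Carlo coalescent averaging of
#' branch lengths; `n_reps` genealogies are simulated per evaluation with a
#' fixed stream seed so repeated evaluations share common random numbers
#' (keeping the likelihood surface smooth in the parameters).
#'
#' @param n_reps number of genealogy replicates per evaluation.
#' @param seed integer stream seed.
#' @return A list of engine settings.
#' @export
engine_settings <- function(n_reps = 20000, seed = 1) {
  stopifnot(n_reps >= 1)
  list(n_reps = as.integer(n_reps), seed = as.numeric(seed))
}

check_params <- function(model, params) {
  params <- as.list(params)
  missing <- setdiff(model$free_params, names(params))
  if (length(missing) > 0)
    stop(sprintf("missing parameter(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  for (nm in model$free_params) {
    v <- params[[nm]]
    b <- model$bounds[[nm]]
    if (!is.finite(v) || v < b[1] || v > b[2])
      stop(sprintf("parameter '%s' = %g outside bounds [%g, %g]",
                   nm, v, b[1], b[2]), call. = FALSE)
  }
  params[model$free_params]
}

#' Expected joint SFS under a demographic model
#'
#' Monte-Carlo expectation of the folded joint site frequency spectrum for a
#' registered model at given parameters: branch lengths subtending each
#' descendant configuration are averaged over `engine$n_reps` coalescent
#' genealogies.  The normalization is arbitrary (the scaling parameter
#' \eqn{\theta} is profiled out downstream by [optimal_scaling_theta()]).
#'
#' @param model a `demog_model` from [get_model()].
#' @param params named list/vector of parameter values within the model's
#'   bounds.
#' @param sizes haploid sample sizes `c(n1, n2)` of the projected spectrum.
#' @param engine engine settings from [engine_settings()].
#' @param fold return the folded spectrum (default) or the unfolded one.
#' @return A `joint_sfs` (folded unless `fold = FALSE`).
#' @export
expected_sfs <- function(model, params, sizes,
                         engine = engine_settings(), fold = TRUE) {
  stopifnot(inherits(model, "demog_model"))
  p <- check_params(model, params)
  sizes <- as.integer(sizes)
  if (length(sizes) != 2L || sum(sizes) < 2L)
    stop("`sizes` must be a pair of haploid sample sizes summing to >= 2",
         call. = FALSE)
  sch <- model$builder(p)
  counts <- cpp_branch_jsfs(sizes[1L], sizes[2L], sch$len, sch$s1, sch$r1,
                            sch$s2, sch$r2, sch$m12, sch$m21, sch$nuA,
                            engine$n_reps, engine$seed)
  out <- jsfs(counts, folded = FALSE)
  if (fold) fold_jsfs(out) else out
}

#' Multiplicative parameter perturbation
#'
#' Each coordinate is multiplied by `2^u` with `u` uniform on
#' `[-fold, +fold]`, then clipped to its bounds — the starting-point
#' dispersal step of the multi-round optimization protocol.
#'
#' @param p named numeric vector of parameter values.
#' @param fold non-negative perturbation magnitude (in log2 units).
#' @param bounds named list of `(lower, upper)` pairs matching `p`.
#' @param seed integer seed.
#' @return Perturbed, clipped parameter vector.
#' @export
perturb_params <- function(p, fold, bounds, seed) {
  stopifnot(fold >= 0)
  p <- unlist(p)
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
    code
  }
  u <- withr_seed(runif(length(p), -fold, fold))
  out <- p * 2^u
  for (i in seq_along(out)) {
    b <- bounds[[names(p)[i]]]
    out[i] <- min(max(out[i], b[1]), b[2])
  }
  out
}
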