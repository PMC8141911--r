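#' Multi-round perturbation fit of a demographic model
#'
#' Implements the staged optimization protocol used for SFS model fitting:
#' round 1 starts from `replicates[1]` perturbations of random (or supplied)
#' starting values at `folds[1]`; every later round perturbs the best
#' parameters of the previous round at its own fold.  Each replicate runs a
#' bounded derivative-free Nelder-Mead search in log-parameter space on the
#' Poisson/multinomial composite likelihood
#' [loglik_multinom()]`(data, `[expected_sfs()]`(...))`; the scaling
#' \eqn{\theta} is profiled out, never optimized.  Per-replicate seeds are
#' derived deterministically from `(seed, round, replicate)`, and every
#' replicate of a fit shares one engine stream (common random numbers), so
#' the whole protocol is bit-reproducible.
#'
#' @param data a folded `joint_sfs` (the observed spectrum).
#' @param model a `demog_model` from [get_model()] or
#'   [onepop_size_change_model()].
#' @param protocol list with equal-length numeric vectors `folds` and
#'   `replicates`; the default mirrors the four-round schedule
#'   folds `[3, 2, 2, 1]` with `[10, 20, 30, 60]` replicates.
#' @param seed master integer seed.
#' @param engine engine settings ([engine_settings()]); the default uses
#'   2000 genealogy replicates per likelihood evaluation, a cost/accuracy
#'   compromise for iterated fitting (raise `n_reps` for final estimates).
#' @param start optional named starting values; the default is the neutral
#'   reference point in diffusion units (sizes 1, times 0.5, migration 1,
#'   `s = 0.25`), clipped into each model's bounds.
#' @param maxit maximum objective evaluations per replicate.
#' @param refine_factor every replicate's candidate (its Nelder-Mead end
#'   point and its starting point) is scored with `refine_factor` times the
#'   engine replicates on the same stream; replicates, rounds and the final
#'   report are compared on these low-noise scores, so selection does not
#'   chase Monte-Carlo noise while the search itself stays cheap.
#' @return A `demog_fit` with elements `model_name`, `best_params`,
#'   `log_likelihood` (the refined evaluation at the best parameters),
#'   `search_log_likelihood` (the maximum over all protocol replicates),
#'   `theta_hat`, `round_trace`, `k` and `seed`.
#' @export
fit_model_multiround <- function(data, model,
                                 protocol = list(folds = c(3, 2, 2, 1),
                                                 replicates = c(10, 20, 30, 60)),
                                 seed = 1,
                                 engine = engine_settings(n_reps = 2000),
                                 start = NULL, maxit = 400,
                                 refine_factor = 8) {
  stopifnot(inherits(data, "joint_sfs"), inherits(model, "demog_model"))
  if (length(protocol$folds) != length(protocol$replicates))
    stop("protocol folds and replicates must have equal length", call. = FALSE)
  if (!data$folded) stop("fit expects a folded data spectrum", call. = FALSE)
  sizes <- c(data$n1, data$n2)
  bounds <- model$bounds
  lo <- log(pmax(vapply(bounds, `[`, numeric(1), 1L), 1e-6))
  hi <- log(vapply(bounds, `[`, numeric(1), 2L))
  if (is.null(start)) {
    # neutral starting point in diffusion units: sizes at the reference
    # scale, times at half a coalescent unit, modest migration and an even
    # split -- clipped into each model's bounds
    canonical <- function(nm, b) {
      v <- switch(sub("[0-9]+$", "", nm),
                  nu = 1, nuA = 1, T = 0.5, s = 0.25, m = 1,
                  sqrt(pmax(b[1], 1e-2) * b[2]))
      min(max(v, b[1]), b[2])
    }
    start <- vapply(model$free_params,
                    function(nm) canonical(nm, bounds[[nm]]), numeric(1))
  }
  start <- unlist(start)[model$free_params]

  eng <- engine_settings(n_reps = engine$n_reps,
                         seed = derive_seed(seed, 101))
  eng_fine <- engine_settings(n_reps = refine_factor * engine$n_reps,
                              seed = eng$seed)
  score <- function(pvec) {  # low-noise evaluation used for selection
    m <- expected_sfs(model, as.list(pvec), sizes, engine = eng_fine)
    loglik_multinom(data, m)
  }
  objective <- function(z) {
    pen <- sum(pmax(0, z - hi)^2 + pmax(0, lo - z)^2)
    zc <- pmin(pmax(z, lo), hi)
    p <- as.list(exp(zc))
    names(p) <- model$free_params
    m <- expected_sfs(model, p, sizes, engine = eng)
    ll <- loglik_multinom(data, m)
    if (!is.finite(ll)) return(1e12)
    -ll + 1e4 * pen
  }

  best <- NULL
  best_ll <- -Inf
  best_search_ll <- -Inf
  round_trace <- numeric(0)
  failures <- 0L
  for (r in seq_along(protocol$folds)) {
    fold <- protocol$folds[r]
    center <- if (r == 1L) start else best
    round_best_ll <- -Inf
    for (rep in seq_len(protocol$replicates[r])) {
      p0 <- perturb_params(center, fold, bounds,
                           seed = derive_seed(seed, r, rep))
      res <- tryCatch(
        suppressWarnings(  # Nelder-Mead in 1-D warns but works; the
                           # multi-start protocol is the global search
          optim(log(p0), objective, method = "Nelder-Mead",
                control = list(maxit = maxit, reltol = 1e-7))),
        error = function(e) NULL)
      if (is.null(res)) { failures <- failures + 1L; next }
      if (-res$value > best_search_ll) best_search_ll <- -res$value
      cand <- exp(pmin(pmax(res$par, lo), hi))
      names(cand) <- model$free_params
      for (pv in list(cand, p0)) {
        ll <- score(pv)
        if (ll > round_best_ll) round_best_ll <- ll
        if (ll > best_ll) {
          best_ll <- ll
          best <- pv
        }
      }
    }
    if (is.null(best))
      stop("all optimizer replicates failed", call. = FALSE)
    round_trace <- c(round_trace, max(round_best_ll, best_ll))
  }

  m_best <- expected_sfs(model, as.list(best), sizes, engine = eng_fine)
  structure(
    list(model_name = model$name,
         best_params = best,
         log_likelihood = best_ll,
         search_log_likelihood = best_search_ll,
         theta_hat = optimal_scaling_theta(data, m_best),
         round_trace = round_trace,
         k = model$k,
         n_failed = failures,
         seed = seed),
    class = "demog_fit"
  )
}

#' @export
print.demog_fit <- function(x, ...) {
  cat(sprintf("<demog_fit> %s: log-L = %.4f, theta = %.4g\n", x$model_name,
              x$log_likelihood, x$theta_hat))
  print(round(x$best_params, 4))
  invisible(x)
}

#' @export
tidy.demog_fit <- function(x, ...) {
  tibble::tibble(term = names(x$best_params),
                 estimate = unname(x$best_params))
}

#' @export
glance.demog_fit <- function(x, ...) {
  tibble::tibble(model = x$model_name, k = x$k,
                 log_likelihood = x$log_likelihood,
                 AIC = 2 * x$k - 2 * x$log_likelihood,
                 theta_hat = x$theta_hat)
}

#' Model selection by AIC and Akaike weights
#'
#' Ranks a set of fitted demographic models: `AIC = 2k - 2 logL`,
#' `delta_AIC = AIC - min(AIC)` and Akaike weights
#' \eqn{\omega_i = \exp(-\Delta_i / 2) / \sum_j \exp(-\Delta_j / 2)}.
#' `k` counts only the free demographic parameters (the profiled scaling
#' \eqn{\theta} is excluded).
#'
#' @param fits list of `demog_fit` objects (distinct models).
#' @return A tibble sorted by AIC with columns `model`, `k`,
#'   `log_likelihood`, `AIC`, `delta_AIC`, `akaike_weight`, `theta_hat`.
#' @export
model_selection_table <- function(fits) {
  if (inherits(fits, "demog_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, logical(1),
                                          "demog_fit")))
  nm <- vapply(fits, `[[`, character(1), "model_name")
  if (anyDuplicated(nm)) stop("duplicate model names", call. = FALSE)
  tbl <- tibble::tibble(
    model = nm,
    k = vapply(fits, `[[`, numeric(1), "k"),
    log_likelihood = vapply(fits, `[[`, numeric(1), "log_likelihood"),
    theta_hat = vapply(fits, `[[`, numeric(1), "theta_hat")
  )
  tbl$AIC <- 2 * tbl$k - 2 * tbl$log_likelihood
  tbl$delta_AIC <- tbl$AIC - min(tbl$AIC)
  w <- exp(-tbl$delta_AIC / 2)
  tbl$akaike_weight <- w / sum(w)
  dplyr::arrange(
    dplyr::select(tbl, "model", "k", "log_likelihood", "AIC", "delta_AIC",
                  "akaike_weight", "theta_hat"),
    .data$AIC)
}
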