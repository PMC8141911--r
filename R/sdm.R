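#' Extract layer values at grid cells
#'
#' @param layers named list of co-registered single-layer `climate_grid`s.
#' @param cells tibble with `row` and `col` columns.
#' @return `cells` with one numeric column per layer appended.
#' @export
extract_layer_values <- function(layers, cells) {
  stopifnot(all(c("row", "col") %in% names(cells)))
  out <- tibble::as_tibble(cells)
  for (nm in names(layers)) {
    v <- layers[[nm]]$values[, , 1]
    out[[nm]] <- v[cbind(cells$row, cells$col)]
  }
  out
}

mask_matrix <- function(m) {
  if (inherits(m, "climate_grid")) m <- m$values[, , 1]
  m <- as.matrix(m)
  !is.na(m) & m != 0
}

#' Draw pseudo-absence cells
#'
#' Samples `n` distinct cells uniformly from the domain after removing every
#' exclusion mask (e.g. the current range, refugial areas, glaciated areas).
#'
#' @param domain_mask `climate_grid` or matrix; non-zero/non-missing cells
#'   are available.
#' @param n number of cells to draw.
#' @param exclusion_masks list of masks (same geometry) whose non-zero cells
#'   are excluded.
#' @param seed integer seed.
#' @return A tibble with columns `row` and `col`.
#' @export
draw_pseudoabsences <- function(domain_mask, n, exclusion_masks = list(),
                                seed = 1) {
  dom <- mask_matrix(domain_mask)
  for (ex in exclusion_masks) dom <- dom & !mask_matrix(ex)
  avail <- which(dom)
  if (length(avail) < n)
    stop(sprintf("only %d cells available for %d pseudo-absences",
                 length(avail), n), call. = FALSE)
  withr_seed(derive_seed(seed, 47), {
    cells <- sample(avail, n)
  })
  tibble::tibble(row = ((cells - 1L) %% nrow(dom)) + 1L,
                 col = ((cells - 1L) %/% nrow(dom)) + 1L)
}

#' Pseudo-absence GLM of occurrence probability
#'
#' Binomial logit GLM with an intercept plus linear and quadratic terms for
#' each predictor, fitted by iteratively reweighted least squares to a
#' convergence tolerance of 1e-8.  Predictors are standardized internally
#' (z-scores of the fitting data) so the quadratic terms are well scaled.
#' Perfect separation is detected and flagged; the coefficients reached at
#' the iteration cap are returned.
#'
#' Presences and absences are given either as cell tables (`row`, `col`;
#' values are then extracted from `layers`) or as tables that already carry
#' one column per predictor (used when presences represent historic
#' climates that no current cell attains).
#'
#' @param presences,absences tibbles (see above).
#' @param layers named list of co-registered single-layer `climate_grid`s;
#'   an empty list fits an intercept-only model.
#' @param seed integer recorded in the fit metadata.
#' @return An `sdm_model`.
#' @export
fit_occurrence_glm <- function(presences, absences, layers = list(),
                               seed = NA_integer_) {
  pred_names <- names(layers)
  prep <- function(tbl) {
    tbl <- tibble::as_tibble(tbl)
    if (length(pred_names) > 0 && !all(pred_names %in% names(tbl)))
      tbl <- extract_layer_values(layers, tbl)
    tbl
  }
  pres <- prep(presences); abs <- prep(absences)
  if (nrow(pres) == 0 || nrow(abs) == 0)
    stop("both presences and absences must be non-empty", call. = FALSE)
  df <- dplyr::bind_rows(
    dplyr::mutate(pres[, pred_names, drop = FALSE], y = 1L),
    dplyr::mutate(abs[, pred_names, drop = FALSE], y = 0L)
  )
  df <- df[complete.cases(df), , drop = FALSE]
  centers <- vapply(pred_names, function(p) mean(df[[p]]), numeric(1))
  scales <- vapply(pred_names, function(p) {
    s <- sd(df[[p]]); if (is.na(s) || s == 0) 1 else s
  }, numeric(1))
  for (p in pred_names) df[[p]] <- (df[[p]] - centers[[p]]) / scales[[p]]
  form <- if (length(pred_names) == 0) y ~ 1 else
    stats::as.formula(paste("y ~",
      paste(sprintf("%s + I(%s^2)", pred_names, pred_names), collapse = " + ")))
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(form, data = df, family = binomial(),
        control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  # complete separation: the model fits the labels perfectly
  if (!separated && (!fit$converged || fit$deviance < 1e-6)) separated <- TRUE
  structure(
    list(fit = fit, predictors = pred_names, centers = centers,
         scales = scales, separated = separated,
         n_presence = sum(df$y == 1), n_absence = sum(df$y == 0),
         presence_data = pres, seed = seed),
    class = "sdm_model"
  )
}

#' @export
print.sdm_model <- function(x, ...) {
  cat(sprintf("<sdm_model> %d presences / %d absences; predictors: %s%s\n",
              x$n_presence, x$n_absence,
              if (length(x$predictors)) paste(x$predictors, collapse = ", ")
              else "(intercept only)",
              if (x$separated) " [separation flagged]" else ""))
  invisible(x)
}

#' @export
tidy.sdm_model <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' @export
glance.sdm_model <- function(x, ...) {
  tibble::tibble(n_presence = x$n_presence, n_absence = x$n_absence,
                 null.deviance = x$fit$null.deviance,
                 deviance = x$fit$deviance, AIC = x$fit$aic,
                 separated = x$separated)
}

#' Predict occurrence probability
#'
#' @param object an `sdm_model`.
#' @param newdata tibble with one column per predictor, or a named list of
#'   `climate_grid` layers (returns a probability grid).
#' @param ... unused.
#' @return Numeric vector in `[0, 1]`, or a `climate_grid` when `newdata`
#'   is a layer list.
#' @export
predict.sdm_model <- function(object, newdata, ...) {
  if (is.list(newdata) && !is.data.frame(newdata) &&
      all(vapply(newdata, inherits, logical(1), "climate_grid"))) {
    tmpl <- newdata[[1]]
    d <- grid_dim(tmpl)
    cells <- tibble::tibble(row = rep(seq_len(d[1]), times = d[2]),
                            col = rep(seq_len(d[2]), each = d[1]))
    vals <- extract_layer_values(newdata, cells)
    p <- predict(object, vals)
    return(with_values(tmpl, matrix(p, nrow = d[1]), kind = "derived"))
  }
  df <- tibble::as_tibble(newdata)
  for (pnm in object$predictors)
    df[[pnm]] <- (df[[pnm]] - object$centers[[pnm]]) / object$scales[[pnm]]
  as.numeric(predict(object$fit, newdata = df, type = "response"))
}

#' Augment an SDM with refugial presences and refit
#'
#' For each refugial area, the historic-climate cell with the highest
#' occurrence probability under the current model is added as a presence
#' (carrying its historic climate values).  Pseudo-absences are regenerated
#' as `n_each` cells from the historic and `n_each` from the current
#' climate, excluding the refugial areas, glaciated areas and the current
#' distribution, and the GLM is refitted.
#'
#' @param model an `sdm_model` fitted on current climate.
#' @param refugial_areas list of masks (one per refugial area).
#' @param historic_layers,layers_current named lists of single-layer
#'   `climate_grid`s (same predictor names as the model).
#' @param domain_mask availability mask for pseudo-absence drawing.
#' @param exclusion_masks additional exclusions (glaciated areas, current
#'   distribution); refugial areas are always excluded.
#' @param n_each pseudo-absences per climate (historic and current).
#' @param seed integer seed.
#' @return A refitted `sdm_model`; the added presences are in
#'   `$refugial_presences`.
#' @export
augment_with_refugia <- function(model, refugial_areas, historic_layers,
                                 layers_current, domain_mask,
                                 exclusion_masks = list(), n_each = 5000,
                                 seed = 1) {
  stopifnot(inherits(model, "sdm_model"), length(refugial_areas) >= 1)
  added <- list()
  for (k in seq_along(refugial_areas)) {
    mm <- mask_matrix(refugial_areas[[k]])
    cells <- which(mm, arr.ind = TRUE)
    if (nrow(cells) == 0)
      stop(sprintf("refugial area %d is empty", k), call. = FALSE)
    ct <- tibble::tibble(row = cells[, 1], col = cells[, 2])
    vals <- extract_layer_values(historic_layers, ct)
    p <- predict(model, vals)
    best <- which.max(p)
    added[[k]] <- vals[best, c("row", "col", model$predictors)]
  }
  added <- dplyr::bind_rows(added)

  excl <- c(refugial_areas, exclusion_masks)
  abs_hist <- draw_pseudoabsences(domain_mask, n_each, excl,
                                  seed = derive_seed(seed, 53))
  abs_cur <- draw_pseudoabsences(domain_mask, n_each, excl,
                                 seed = derive_seed(seed, 59))
  abs_all <- dplyr::bind_rows(
    extract_layer_values(historic_layers, abs_hist),
    extract_layer_values(layers_current, abs_cur)
  )
  pres_all <- dplyr::bind_rows(
    model$presence_data[, intersect(names(model$presence_data),
                                    c("row", "col", model$predictors))],
    added
  )
  out <- fit_occurrence_glm(pres_all, abs_all, layers_current, seed = seed)
  out$refugial_presences <- added
  out
}
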