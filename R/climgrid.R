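#' Gridded climate / elevation layers
#'
#' A `climate_grid` wraps a numeric matrix (rows = y from the top, columns =
#' x) or a 3D array with a month/time axis, with a cell size, a lower-left
#' origin, a variable kind and `NA` as the missing marker.  Grids are
#' "co-registered" when cell size, origin and shape agree.
#'
#' @param values numeric matrix (ny x nx) or array (ny x nx x months).
#' @param cellsize cell edge length (degrees or meters; one unit per
#'   analysis).
#' @param xll,yll lower-left corner coordinates of the grid.
#' @param kind one of `"t_min"`, `"t_max"`, `"t_mean"`, `"precip"`,
#'   `"elevation"`, `"derived"`.
#' @param start_year first year of a monthly time series (arrays whose third
#'   dimension is `12 * n_years`).
#' @return A `climate_grid`.
#' @export
climate_grid <- function(values, cellsize = 1, xll = 0, yll = 0,
                         kind = c("t_mean", "t_min", "t_max", "precip",
                                  "elevation", "derived"),
                         start_year = NULL) {
  kind <- match.arg(kind)
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (kind == "precip" && any(values < 0, na.rm = TRUE))
    stop("precipitation must be non-negative", call. = FALSE)
  structure(
    list(values = values, cellsize = cellsize, xll = xll, yll = yll,
         kind = kind, start_year = start_year),
    class = "climate_grid"
  )
}

#' @export
print.climate_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<climate_grid> %s: %d x %d cells (x %d layers), cellsize %g, origin (%g, %g)\n",
              x$kind, d[1], d[2], d[3], x$cellsize, x$xll, x$yll))
  invisible(x)
}

grid_dim <- function(g) dim(g$values)

# x/y coordinates of cell centers; row 1 is the top row
grid_centers <- function(g) {
  d <- grid_dim(g)
  x <- g$xll + (seq_len(d[2]) - 0.5) * g$cellsize
  y <- g$yll + (d[1] - seq_len(d[1]) + 0.5) * g$cellsize
  list(x = x, y = y)
}

same_registration <- function(a, b) {
  da <- grid_dim(a); db <- grid_dim(b)
  isTRUE(all.equal(da[1:2], db[1:2])) &&
    isTRUE(all.equal(c(a$cellsize, a$xll, a$yll),
                     c(b$cellsize, b$xll, b$yll)))
}

with_values <- function(g, values, kind = g$kind) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  climate_grid(values, cellsize = g$cellsize, xll = g$xll, yll = g$yll,
               kind = kind, start_year = NULL)
}

#' Plain-text grid I/O
#'
#' The exchange format has a four-line header (`ncols`, `nrows`, `cellsize`,
#' `nodata`) followed by the rows of the grid, top row first; multi-layer
#' grids repeat the block per layer separated by a `layer <i>` line.
#'
#' @param grid a `climate_grid`.
#' @param path file path.
#' @param kind variable kind to attach on reading.
#' @return `read_grid()` returns a `climate_grid`; `write_grid()` its input,
#'   invisibly.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "climate_grid"))
  d <- grid_dim(grid)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", d[2]), sprintf("nrows %d", d[1]),
               sprintf("cellsize %.10g", grid$cellsize),
               sprintf("xllcorner %.10g", grid$xll),
               sprintf("yllcorner %.10g", grid$yll),
               "nodata -9999"), con)
  for (l in seq_len(d[3])) {
    if (d[3] > 1L) writeLines(sprintf("layer %d", l), con)
    m <- grid$values[, , l]
    m[is.na(m)] <- -9999
    writeLines(apply(m, 1, function(r)
      paste(format(r, digits = 10, trim = TRUE, scientific = FALSE),
            collapse = " ")), con)
  }
  invisible(grid)
}

#' @rdname write_grid
#' @export
read_grid <- function(path, kind = "derived") {
  lines <- readLines(path)
  hdr <- lines[1:6]
  gv <- function(key) as.numeric(sub(paste0(key, " "), "", hdr[grepl(key, hdr)]))
  nc <- gv("ncols"); nr <- gv("nrows"); cs <- gv("cellsize")
  xll <- gv("xllcorner"); yll <- gv("yllcorner")
  body <- lines[-(1:6)]
  is_layer <- grepl("^layer ", body)
  blocks <- if (any(is_layer)) split(body[!is_layer],
                                     cumsum(is_layer)[!is_layer])
            else list(body)
  arr <- array(NA_real_, c(nr, nc, length(blocks)))
  for (l in seq_along(blocks)) {
    m <- do.call(rbind, lapply(blocks[[l]], function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])))
    m[m == -9999] <- NA
    arr[, , l] <- m
  }
  climate_grid(arr, cellsize = cs, xll = xll, yll = yll, kind = kind)
}

#' 30-year window climatology of a monthly series
#'
#' Per-cell, per-calendar-month arithmetic mean over the years of `window`.
#'
#' @param series a `climate_grid` whose third dimension holds consecutive
#'   months starting January of `start_year`.
#' @param window inclusive year range `c(first, last)`.
#' @return A 12-layer `climate_grid` climatology.
#' @export
window_mean <- function(series, window) {
  stopifnot(inherits(series, "climate_grid"))
  if (is.null(series$start_year))
    stop("series must carry a start_year", call. = FALSE)
  d <- grid_dim(series)
  n_years <- d[3] %/% 12L
  years <- series$start_year + seq_len(n_years) - 1L
  sel <- which(years >= window[1] & years <= window[2])
  if (length(sel) == 0 || window[1] < min(years) || window[2] > max(years))
    stop("window outside the span of the series", call. = FALSE)
  out <- array(0, c(d[1], d[2], 12L))
  for (m in 1:12) {
    idx <- (sel - 1L) * 12L + m
    out[, , m] <- apply(series$values[, , idx, drop = FALSE], c(1, 2), mean)
  }
  with_values(series, out)
}

#' Climate anomalies ("deltas") between a historic and a reference state
#'
#' Temperature deltas are differences (`historic - reference`);
#' precipitation deltas are ratios (`historic / reference`).  Ratio cells
#' with a zero reference are set to 1 (no change) and flagged via the
#' `"flagged_cells"` attribute.
#'
#' @param historic,reference co-registered `climate_grid`s of the same kind
#'   and layer count.
#' @param kind `"temperature"` or `"precipitation"`; inferred from the grid
#'   kind when missing.
#' @return A `climate_grid` of deltas.
#' @export
compute_deltas <- function(historic, reference, kind = NULL) {
  stopifnot(inherits(historic, "climate_grid"),
            inherits(reference, "climate_grid"))
  if (!same_registration(historic, reference))
    stop("grids are not co-registered", call. = FALSE)
  if (!identical(grid_dim(historic)[3], grid_dim(reference)[3]))
    stop("layer counts differ", call. = FALSE)
  if (is.null(kind))
    kind <- if (historic$kind == "precip") "precipitation" else "temperature"
  if (kind == "temperature") {
    out <- with_values(historic, historic$values - reference$values,
                       kind = "derived")
    attr(out, "flagged_cells") <- integer(0)
  } else {
    ref <- reference$values
    zero <- which(ref == 0)
    delta <- historic$values / ref
    delta[zero] <- 1
    out <- with_values(historic, delta, kind = "derived")
    attr(out, "flagged_cells") <- zero
  }
  out
}

#' Thin-plate-spline interpolation of a coarse field
#'
#' Fits an exact thin-plate spline (kernel `r^2 log r` plus an affine part)
#' through the non-missing coarse cell centers and evaluates it at the
#' centers of the target grid.  The surface reproduces the node values and
#' any affine field exactly.
#'
#' @param coarse a `climate_grid` (multi-layer grids are interpolated per
#'   layer).
#' @param target_resolution cell size of the output grid (same origin and
#'   extent as `coarse`), or a `climate_grid` whose geometry to match.
#' @return A `climate_grid` at the target geometry.
#' @export
interpolate_field <- function(coarse, target_resolution) {
  stopifnot(inherits(coarse, "climate_grid"))
  d <- grid_dim(coarse)
  cc <- grid_centers(coarse)
  if (inherits(target_resolution, "climate_grid")) {
    tmpl <- target_resolution
    tc <- grid_centers(tmpl)
    out_dim <- grid_dim(tmpl)[1:2]
    geom <- list(cellsize = tmpl$cellsize, xll = tmpl$xll, yll = tmpl$yll)
  } else {
    res <- target_resolution
    extent_x <- d[2] * coarse$cellsize
    extent_y <- d[1] * coarse$cellsize
    nx <- max(1L, round(extent_x / res))
    ny <- max(1L, round(extent_y / res))
    out_dim <- c(ny, nx)
    geom <- list(cellsize = res, xll = coarse$xll, yll = coarse$yll)
    tc <- list(x = geom$xll + (seq_len(nx) - 0.5) * res,
               y = geom$yll + (ny - seq_len(ny) + 0.5) * res)
  }
  pts_out <- cbind(rep(tc$x, each = out_dim[1]),
                   rep(tc$y, times = out_dim[2]))
  out <- array(NA_real_, c(out_dim, d[3]))
  for (l in seq_len(d[3])) {
    z <- coarse$values[, , l]
    ok <- which(!is.na(z))
    if (length(ok) < 3)
      stop("need at least 3 non-missing coarse nodes", call. = FALSE)
    nodes <- cbind(rep(cc$x, each = d[1]), rep(cc$y, times = d[2]))[ok, ,
                                                                    drop = FALSE]
    out[, , l] <- matrix(tps_predict(nodes, z[ok], pts_out), nrow = out_dim[1])
  }
  climate_grid(out, cellsize = geom$cellsize, xll = geom$xll, yll = geom$yll,
               kind = "derived")
}

tps_kernel <- function(r) {
  k <- r^2 * log(r)
  k[r == 0] <- 0
  k
}

tps_predict <- function(nodes, z, new_pts) {
  n <- nrow(nodes)
  D <- as.matrix(stats::dist(nodes))
  K <- tps_kernel(D)
  P <- cbind(1, nodes)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- c(z, 0, 0, 0)
  sol <- solve(A, rhs)
  w <- sol[1:n]; a <- sol[n + 1:3]
  dx <- outer(new_pts[, 1], nodes[, 1], "-")
  dy <- outer(new_pts[, 2], nodes[, 2], "-")
  R <- sqrt(dx^2 + dy^2)
  tps_kernel(R) %*% w + a[1] + a[2] * new_pts[, 1] + a[3] * new_pts[, 2]
}

#' Apply interpolated deltas to a fine reference climatology
#'
#' Temperature: `reference + delta`; precipitation: `reference * delta`
#' (negative products are clamped to zero and flagged).
#'
#' @param fine_reference,fine_delta co-registered `climate_grid`s.
#' @param kind `"temperature"` or `"precipitation"`.
#' @return A `climate_grid`.
#' @export
apply_deltas <- function(fine_reference, fine_delta,
                         kind = c("temperature", "precipitation")) {
  kind <- match.arg(kind)
  stopifnot(inherits(fine_reference, "climate_grid"),
            inherits(fine_delta, "climate_grid"))
  if (!same_registration(fine_reference, fine_delta))
    stop("grids are not co-registered", call. = FALSE)
  if (kind == "temperature") {
    out <- with_values(fine_reference,
                       fine_reference$values + fine_delta$values)
    attr(out, "flagged_cells") <- integer(0)
  } else {
    v <- fine_reference$values * fine_delta$values
    neg <- which(v < 0)
    v[neg] <- 0
    out <- with_values(fine_reference, v)
    attr(out, "flagged_cells") <- neg
  }
  out
}

#' Two-step delta-method downscaling
#'
#' Chains the delta method across three resolutions.  Step 1: anomalies of
#' the coarse paleo series between the historic window and the first
#' reference window are interpolated to the mid-resolution grid and applied
#' to the mid series' first-reference climatology, giving a mid-resolution
#' historic estimate.  Step 2: anomalies of that estimate against the mid
#' series' second-reference climatology are interpolated to the fine grid
#' and applied to the fine climatology.
#'
#' @param paleo_coarse coarse monthly series (`climate_grid` with
#'   `start_year`).
#' @param mid_series mid-resolution monthly series.
#' @param fine_climatology fine 12-layer climatology.
#' @param periods list with year ranges `historic`, `ref1` (overlap of paleo
#'   and mid series) and `ref2` (overlap of mid series and the fine
#'   climatology's base period).
#' @param kind `"temperature"` or `"precipitation"`.
#' @return A fine-resolution 12-layer `climate_grid` for the historic
#'   period.
#' @export
downscale_two_step <- function(paleo_coarse, mid_series, fine_climatology,
                               periods, kind = c("temperature",
                                                 "precipitation")) {
  kind <- match.arg(kind)
  for (nm in c("historic", "ref1", "ref2"))
    if (is.null(periods[[nm]]))
      stop(sprintf("periods$%s is required", nm), call. = FALSE)
  if (paleo_coarse$cellsize <= mid_series$cellsize ||
      mid_series$cellsize <= fine_climatology$cellsize)
    stop("resolutions must be strictly ordered coarse > mid > fine",
         call. = FALSE)
  # step 1: paleo anomalies onto the mid-resolution reference climatology
  hist_clim <- window_mean(paleo_coarse, periods$historic)
  ref_clim <- window_mean(paleo_coarse, periods$ref1)
  d1 <- compute_deltas(hist_clim, ref_clim,
                       kind = if (kind == "temperature") "temperature"
                              else "precipitation")
  d1_mid <- interpolate_field(d1, mid_series)
  mid_ref1 <- window_mean(mid_series, periods$ref1)
  mid_hist <- apply_deltas(mid_ref1, d1_mid, kind)
  # step 2: mid-resolution anomalies onto the fine climatology
  mid_ref2 <- window_mean(mid_series, periods$ref2)
  d2 <- compute_deltas(mid_hist, mid_ref2,
                       kind = if (kind == "temperature") "temperature"
                              else "precipitation")
  d2_fine <- interpolate_field(d2, fine_climatology)
  apply_deltas(fine_climatology, d2_fine, kind)
}

#' Bioclimatic summary variables from monthly climatologies
#'
#' bio1 = annual mean of the monthly mean temperatures; bio4 = standard
#' deviation of the 12 monthly means x 100 (sample SD); bio12 = annual
#' precipitation sum; bio15 = precipitation seasonality, 100 x SD / mean of
#' monthly precipitation (coefficient of variation; cells with zero mean
#' precipitation are flagged missing).
#'
#' @param monthly_temp,monthly_precip 12-layer `climate_grid`s.
#' @return A named list of single-layer `climate_grid`s: `bio1`, `bio4`,
#'   `bio12`, `bio15`.
#' @export
derive_bioclim <- function(monthly_temp, monthly_precip) {
  stopifnot(inherits(monthly_temp, "climate_grid"),
            inherits(monthly_precip, "climate_grid"))
  if (grid_dim(monthly_temp)[3] != 12L || grid_dim(monthly_precip)[3] != 12L)
    stop("12 monthly layers are required", call. = FALSE)
  if (!same_registration(monthly_temp, monthly_precip))
    stop("grids are not co-registered", call. = FALSE)
  tmean <- apply(monthly_temp$values, c(1, 2), mean)
  tsd <- apply(monthly_temp$values, c(1, 2), sd)
  psum <- apply(monthly_precip$values, c(1, 2), sum)
  psd <- apply(monthly_precip$values, c(1, 2), sd)
  pmean <- psum / 12
  p15 <- 100 * psd / pmean
  p15[pmean == 0] <- NA_real_
  list(
    bio1 = with_values(monthly_temp, tmean, kind = "derived"),
    bio4 = with_values(monthly_temp, 100 * tsd, kind = "derived"),
    bio12 = with_values(monthly_precip, psum, kind = "derived"),
    bio15 = with_values(monthly_precip, p15, kind = "derived")
  )
}

#' Topographic roughness as block-wise elevation SD
#'
#' Aggregates a fine elevation grid into coarse cells and returns the
#' population standard deviation of the enclosed fine elevations per coarse
#' cell.  Partial edge blocks use the available fine cells and are flagged
#' via the `"partial_cells"` attribute.
#'
#' @param elevation_fine a single-layer `climate_grid`.
#' @param coarse_cell_size coarse cell size; must be a multiple of the fine
#'   resolution (edge remainders allowed).
#' @return A coarse `climate_grid` of roughness values.
#' @export
topo_roughness <- function(elevation_fine, coarse_cell_size) {
  stopifnot(inherits(elevation_fine, "climate_grid"))
  f <- coarse_cell_size / elevation_fine$cellsize
  if (abs(f - round(f)) > 1e-8)
    stop("fine resolution must divide the coarse cell size", call. = FALSE)
  f <- as.integer(round(f))
  d <- grid_dim(elevation_fine)
  nr <- ceiling(d[1] / f); nc <- ceiling(d[2] / f)
  out <- matrix(NA_real_, nr, nc)
  partial <- integer(0)
  z <- elevation_fine$values[, , 1]
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ri <- ((i - 1L) * f + 1L):min(i * f, d[1])
    cj <- ((j - 1L) * f + 1L):min(j * f, d[2])
    block <- z[ri, cj]
    if (length(block) < f * f) partial <- c(partial, (j - 1L) * nr + i)
    block <- block[!is.na(block)]
    if (length(block) > 0)
      out[i, j] <- sqrt(mean((block - mean(block))^2))  # population SD
  }
  res <- climate_grid(out, cellsize = coarse_cell_size,
                      xll = elevation_fine$xll, yll = elevation_fine$yll,
                      kind = "derived")
  attr(res, "partial_cells") <- partial
  res
}

#' Pairwise collinearity screen of environmental layers
#'
#' Pearson correlations over jointly non-missing cells for every layer pair;
#' pairs with `|r|` above the threshold are flagged, as are pairs involving
#' a constant layer (undefined r).
#'
#' @param layers named list of co-registered single-layer `climate_grid`s.
#' @param threshold flag pairs with `|r|` above this value.
#' @return A tibble with columns `layer1`, `layer2`, `r`, `flagged`.
#' @export
screen_collinearity <- function(layers, threshold = 0.7) {
  stopifnot(length(layers) >= 2)
  nms <- names(layers)
  vals <- lapply(layers, function(g) as.vector(g$values[, , 1]))
  pairs <- combn(length(layers), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    ok <- complete.cases(vals[[i]], vals[[j]])
    r <- if (sd(vals[[i]][ok]) == 0 || sd(vals[[j]][ok]) == 0) NA_real_
         else cor(vals[[i]][ok], vals[[j]][ok])
    tibble::tibble(layer1 = nms[i], layer2 = nms[j], r = r,
                   flagged = is.na(r) || abs(r) > threshold)
  })
  dplyr::bind_rows(rows)
}

#' Raster image of a climate grid
#' @param object a `climate_grid`.
#' @param layer layer index for multi-layer grids.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.climate_grid <- function(object, layer = 1, ...) {
  d <- grid_dim(object)
  cc <- grid_centers(object)
  df <- tibble::tibble(
    x = rep(cc$x, each = d[1]),
    y = rep(cc$y, times = d[2]),
    value = as.vector(object$values[, , layer])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
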