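#' Joint site frequency spectrum objects
#'
#' A `joint_sfs` holds the two-dimensional joint site frequency spectrum
#' (2D-JSFS) of two populations: cell `(i, j)` (0-based) carries the number of
#' SNPs (or expected branch-length mass) at which the derived or minor allele
#' was observed `i` times among `n1` sampled alleles of population 1 and `j`
#' times among `n2` alleles of population 2.  The absorbing corners `(0, 0)`
#' and `(n1, n2)` carry no polymorphism information and are always masked; a
#' folded spectrum additionally masks the redundant major-allele half.
#'
#' A single-population (1D) spectrum is represented with `n2 = 0`.
#'
#' @param counts numeric matrix with `n1 + 1` rows and `n2 + 1` columns,
#'   non-negative.
#' @param folded logical flag; folded spectra combine each cell with its
#'   complement.
#' @param mask logical matrix of the same shape; `TRUE` cells carry no
#'   likelihood weight.  Defaults to the two corners.
#' @return An object of class `joint_sfs`.
#' @examples
#' jsfs(matrix(c(0, 3, 2, 1, 0), ncol = 1))
#' @export
jsfs <- function(counts, folded = FALSE, mask = NULL) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("`counts` must be numeric", call. = FALSE)
  if (any(counts < 0)) stop("SFS counts must be non-negative", call. = FALSE)
  n1 <- nrow(counts) - 1L
  n2 <- ncol(counts) - 1L
  if (is.null(mask)) {
    mask <- matrix(FALSE, n1 + 1L, n2 + 1L)
    mask[1L, 1L] <- TRUE
    mask[n1 + 1L, n2 + 1L] <- TRUE
  }
  mask <- as.matrix(mask)
  if (!identical(dim(mask), dim(counts)))
    stop("`mask` must match the shape of `counts`", call. = FALSE)
  structure(
    list(counts = counts, n1 = n1, n2 = n2,
         folded = isTRUE(folded), mask = mask),
    class = "joint_sfs"
  )
}

#' @export
print.joint_sfs <- function(x, ...) {
  cat(sprintf("<joint_sfs> n1 = %d, n2 = %d, %s; %.6g units of mass in %d unmasked cells\n",
              x$n1, x$n2, if (x$folded) "folded" else "unfolded",
              sum(x$counts[!x$mask]), sum(!x$mask)))
  invisible(x)
}

#' @describeIn jsfs Total mass over unmasked cells.
#' @param x,object a `joint_sfs`.
#' @param ... unused.
#' @export
sfs_mass <- function(x) {
  stopifnot(inherits(x, "joint_sfs"))
  sum(x$counts[!x$mask])
}

#' @export
as_tibble.joint_sfs <- function(x, ...) {
  tibble::tibble(
    i = rep(0:x$n1, times = x$n2 + 1L),
    j = rep(0:x$n2, each = x$n1 + 1L),
    count = as.vector(x$counts),
    masked = as.vector(x$mask)
  )
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Fold a joint site frequency spectrum
#'
#' Folding removes the dependence on ancestral-state calls: each cell
#' `(i, j)` is combined with its complement `(n1 - i, n2 - j)` and the
#' redundant (major-allele) half of the spectrum is masked.  A cell is kept
#' when its scaled allele frequency `i/n1 + j/n2` is below that of its
#' complement; cells exactly on the fold line keep the lexicographically
#' smaller member of each pair, and self-complementary cells are kept without
#' doubling.
#'
#' @param sfs an unfolded `joint_sfs`.
#' @return A folded `joint_sfs` with the same total unmasked mass.
#' @export
fold_jsfs <- function(sfs) {
  stopifnot(inherits(sfs, "joint_sfs"))
  if (sfs$folded) stop("spectrum is already folded", call. = FALSE)
  n1 <- sfs$n1; n2 <- sfs$n2
  counts <- sfs$counts
  out <- matrix(0, n1 + 1L, n2 + 1L)
  mask <- matrix(TRUE, n1 + 1L, n2 + 1L)
  freq <- function(i, j) {
    f <- 0
    if (n1 > 0) f <- f + i / n1
    if (n2 > 0) f <- f + j / n2
    f
  }
  for (i in 0:n1) for (j in 0:n2) {
    ci <- n1 - i; cj <- n2 - j
    f <- freq(i, j); fc <- freq(ci, cj)
    selfc <- (i == ci && j == cj)
    keep <- if (selfc) TRUE
      else if (f < fc) TRUE
      else if (f > fc) FALSE
      else (i < ci || (i == ci && j < cj))  # on the fold line: keep lex-min
    if (!keep) next
    out[i + 1L, j + 1L] <-
      if (selfc) counts[i + 1L, j + 1L]
      else counts[i + 1L, j + 1L] + counts[ci + 1L, cj + 1L]
    mask[i + 1L, j + 1L] <- FALSE
  }
  # corners stay masked; propagate any explicit input mask onto kept cells
  mask[1L, 1L] <- TRUE
  premask <- sfs$mask | sfs$mask[(n1 + 1L):1L, (n2 + 1L):1L, drop = FALSE]
  mask <- mask | premask
  jsfs(out, folded = TRUE, mask = mask)
}

#' Down-project a joint site frequency spectrum
#'
#' Redistributes the mass of each cell `(d1, d2)` onto the smaller sample
#' sizes `target = c(m1, m2)` using the hypergeometric expectation: drawing
#' `m` alleles without replacement from `n` of which `d` are derived yields
#' `k` derived with probability `C(d, k) C(n - d, m - k) / C(n, m)`.  The
#' projection is deterministic (fractional mass, no resampling) and conserves
#' total mass exactly; mass landing in the monomorphic corners is recorded
#' there and masked.
#'
#' @param sfs an unfolded `joint_sfs`.
#' @param target integer pair `(m1, m2)` of projected haploid sizes,
#'   elementwise at most `(n1, n2)`.
#' @return An unfolded `joint_sfs` of shape `(m1 + 1) x (m2 + 1)`.
#' @export
project_jsfs <- function(sfs, target) {
  stopifnot(inherits(sfs, "joint_sfs"))
  if (sfs$folded) stop("project before folding: spectrum is folded", call. = FALSE)
  target <- as.integer(target)
  if (length(target) != 2L) stop("`target` must be a pair", call. = FALSE)
  m1 <- target[1L]; m2 <- target[2L]
  if (m1 > sfs$n1 || m2 > sfs$n2)
    stop("projection target larger than current sample sizes", call. = FALSE)
  if (m1 < 0 || m2 < 0) stop("projection sizes must be non-negative", call. = FALSE)
  W1 <- projection_weights(sfs$n1, m1)
  W2 <- projection_weights(sfs$n2, m2)
  out <- t(W1) %*% sfs$counts %*% W2
  jsfs(out, folded = FALSE)
}

# (n + 1) x (m + 1) matrix; row d, column k = P(k derived | d of n, draw m).
projection_weights <- function(n, m) {
  W <- matrix(0, n + 1L, m + 1L)
  for (d in 0:n) {
    k <- 0:m
    W[d + 1L, ] <- exp(lchoose(d, k) + lchoose(n - d, m - k) - lchoose(n, m))
  }
  W
}

#' Poisson/multinomial composite log-likelihood of an SFS
#'
#' Compares an observed spectrum to a model spectrum of arbitrary
#' normalization.  The model is first scaled by the optimal
#' \eqn{\hat\theta = \sum D / \sum M} over unmasked cells and the Poisson
#' log-likelihood \eqn{\sum_i [D_i \log \lambda_i - \lambda_i - \log D_i!]}
#' is returned (the Poisson form of the multinomial likelihood; invariant to
#' the model's normalization).
#'
#' @param data,model `joint_sfs` objects of identical shape, folded state and
#'   mask.
#' @return The log-likelihood (scalar).  `-Inf` when a model cell is zero
#'   where data are positive; `0` for all-zero data (with
#'   \eqn{\hat\theta = 0} by convention).
#' @export
loglik_multinom <- function(data, model) {
  stopifnot(inherits(data, "joint_sfs"), inherits(model, "joint_sfs"))
  if (!identical(dim(data$counts), dim(model$counts)))
    stop("data and model spectra have different shapes", call. = FALSE)
  if (!identical(data$folded, model$folded))
    stop("data and model spectra have different folded states", call. = FALSE)
  if (!identical(data$mask, model$mask))
    stop("data and model spectra have different masks", call. = FALSE)
  keep <- !data$mask
  D <- data$counts[keep]
  M <- model$counts[keep]
  sD <- sum(D)
  if (sD == 0) return(0)
  sM <- sum(M)
  if (sM <= 0) stop("model spectrum has no mass on unmasked cells", call. = FALSE)
  lam <- (sD / sM) * M
  if (any(lam == 0 & D > 0)) return(-Inf)
  pos <- D > 0
  sum(D[pos] * log(lam[pos])) - sum(lam) - sum(lgamma(D[pos] + 1))
}

#' Optimal scaling between a data and a model spectrum
#'
#' \eqn{\hat\theta = \sum D / \sum M} over unmasked cells: the multiplier
#' bringing an arbitrarily normalized model spectrum onto the scale of the
#' data, profiled out of the SFS likelihood.
#'
#' @inheritParams loglik_multinom
#' @return The scalar \eqn{\hat\theta}.
#' @export
optimal_scaling_theta <- function(data, model) {
  stopifnot(inherits(data, "joint_sfs"), inherits(model, "joint_sfs"))
  if (!identical(dim(data$counts), dim(model$counts)))
    stop("data and model spectra have different shapes", call. = FALSE)
  if (!identical(data$mask, model$mask))
    stop("data and model spectra have different masks", call. = FALSE)
  keep <- !data$mask
  sM <- sum(model$counts[keep])
  if (sM == 0) stop("model spectrum sums to zero over unmasked cells", call. = FALSE)
  sum(data$counts[keep]) / sM
}

#' Read and write the flat-text SFS exchange format
#'
#' Three lines: `"<n1+1> <n2+1> folded|unfolded"`, the row-major counts, and
#' the row-major 0/1 mask.  The round-trip is bit-exact for integer-valued
#' spectra and full double precision is written for fractional mass.
#'
#' @param sfs a `joint_sfs`.
#' @param path file path.
#' @return `write_sfs()` returns `sfs` invisibly; `read_sfs()` returns a
#'   `joint_sfs`.
#' @export
write_sfs <- function(sfs, path) {
  stopifnot(inherits(sfs, "joint_sfs"))
  lines <- c(
    sprintf("%d %d %s", sfs$n1 + 1L, sfs$n2 + 1L,
            if (sfs$folded) "folded" else "unfolded"),
    paste(format(as.vector(t(sfs$counts)), digits = 17, trim = TRUE,
                 scientific = FALSE), collapse = " "),
    paste(as.integer(as.vector(t(sfs$mask))), collapse = " ")
  )
  writeLines(lines, path)
  invisible(sfs)
}

#' @rdname write_sfs
#' @export
read_sfs <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("malformed SFS file", call. = FALSE)
  hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  d1 <- as.integer(hdr[1L]); d2 <- as.integer(hdr[2L])
  folded <- identical(hdr[3L], "folded")
  cnt <- as.numeric(strsplit(trimws(lines[2L]), "\\s+")[[1L]])
  msk <- as.integer(strsplit(trimws(lines[3L]), "\\s+")[[1L]])
  if (length(cnt) != d1 * d2 || length(msk) != d1 * d2)
    stop("SFS file does not match its stated shape", call. = FALSE)
  counts <- matrix(cnt, nrow = d1, ncol = d2, byrow = TRUE)
  mask <- matrix(as.logical(msk), nrow = d1, ncol = d2, byrow = TRUE)
  jsfs(counts, folded = folded, mask = mask)
}

#' Heatmap of a joint SFS
#'
#' @param object a `joint_sfs`.
#' @param ... unused.
#' @return A ggplot object (log1p-scaled fill; masked cells blank).
#' @export
autoplot.joint_sfs <- function(object, ...) {
  df <- as_tibble(object)
  df$count[df$masked] <- NA_real_
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = log1p(.data$count))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "allele count, population 2",
                  y = "allele count, population 1",
                  fill = "log1p(count)") +
    ggplot2::theme_minimal()
}
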