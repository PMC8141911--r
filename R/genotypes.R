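#' Diploid genotype matrices with population labels
#'
#' The central SNP container: biallelic genotypes coded 0/1/2 (copies of the
#' alternate allele) or `NA` for missing calls, one row per individual and one
#' column per site, together with per-genotype sequencing depth, a population
#' label per individual, and per-site locus/position coordinates.
#'
#' @param gt integer matrix (individuals x sites) of 0, 1, 2 or `NA`.
#' @param pop character vector of population labels, one per individual.
#' @param depth non-negative integer matrix of per-genotype depths, same shape
#'   as `gt`; defaults to a constant depth of 10.
#' @param sites data frame with columns `locus` and `pos` (one row per site);
#'   defaults to a single locus with consecutive positions.
#' @param ind character vector of individual identifiers.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(gt, pop, depth = NULL, sites = NULL, ind = NULL) {
  gt <- as.matrix(gt)
  storage.mode(gt) <- "integer"
  if (!all(gt %in% c(0L, 1L, 2L) | is.na(gt)))
    stop("genotypes must be 0, 1, 2 or NA", call. = FALSE)
  n_ind <- nrow(gt); n_site <- ncol(gt)
  if (length(pop) != n_ind)
    stop("`pop` must have one label per individual", call. = FALSE)
  if (is.null(depth)) depth <- matrix(10L, n_ind, n_site)
  depth <- as.matrix(depth)
  storage.mode(depth) <- "integer"
  if (!identical(dim(depth), dim(gt)))
    stop("`depth` must match the shape of `gt`", call. = FALSE)
  if (any(depth < 0, na.rm = TRUE)) stop("depths must be >= 0", call. = FALSE)
  if (is.null(sites))
    sites <- tibble::tibble(locus = rep("L1", n_site), pos = seq_len(n_site))
  sites <- tibble::as_tibble(sites)
  if (nrow(sites) != n_site)
    stop("`sites` must have one row per site", call. = FALSE)
  if (is.null(ind)) ind <- sprintf("ind%03d", seq_len(n_ind))
  rownames(gt) <- rownames(depth) <- ind
  structure(
    list(gt = gt, depth = depth, pop = as.character(pop),
         sites = sites, ind = as.character(ind)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d sites; populations: %s; %.1f%% missing\n",
              nrow(x$gt), ncol(x$gt),
              paste(sprintf("%s (%d)", names(table(x$pop)), table(x$pop)),
                    collapse = ", "),
              100 * mean(is.na(x$gt))))
  invisible(x)
}

#' @export
as_tibble.genotype_matrix <- function(x, ...) {
  tibble::tibble(
    ind = rep(x$ind, times = ncol(x$gt)),
    pop = rep(x$pop, times = ncol(x$gt)),
    locus = rep(x$sites$locus, each = nrow(x$gt)),
    pos = rep(x$sites$pos, each = nrow(x$gt)),
    genotype = as.integer(x$gt),
    depth = as.integer(x$depth)
  )
}

#' Number of sites / individuals of a genotype matrix
#' @param gm a `genotype_matrix`.
#' @return Integer count.
#' @export
n_sites <- function(gm) ncol(gm$gt)

#' @rdname n_sites
#' @export
n_individuals <- function(gm) nrow(gm$gt)
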