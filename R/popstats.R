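#' Per-unit diversity descriptors
#'
#' Computes, for each population or group: the number of sites with at least
#' one called genotype (`sites_recovered`), the percentage of polymorphic
#' sites, mean expected heterozygosity \eqn{2p(1-p)}, nucleotide diversity
#' \eqn{\pi} with the unbiased \eqn{n/(n-1)} correction on called alleles,
#' and the number of private alleles (alleles observed in that unit and in
#' no other unit of the analysis).  Sites with fewer than two called alleles
#' in a unit are skipped for that unit's frequency-based statistics.
#'
#' @param gm a [genotype_matrix()].
#' @param grouping optional named vector or data frame (`ind`, `unit`)
#'   overriding the population labels.
#' @return A tibble with one row per unit: `unit`, `sites_recovered`,
#'   `pct_polymorphic`, `expected_heterozygosity`, `nucleotide_diversity_pi`,
#'   `private_alleles`.
#' @export
diversity_stats <- function(gm, grouping = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  units <- gm$pop
  if (!is.null(grouping)) {
    if (is.data.frame(grouping)) {
      units <- grouping$unit[match(gm$ind, grouping$ind)]
    } else {
      units <- unname(grouping[gm$ind])
    }
    if (anyNA(units))
      stop("grouping must assign every individual to exactly one unit",
           call. = FALSE)
  }
  ulev <- sort(unique(units))
  n_site <- n_sites(gm)

  # per-unit per-site called allele counts and derived counts
  called <- matrix(0L, length(ulev), n_site)
  derived <- matrix(0L, length(ulev), n_site)
  for (u in seq_along(ulev)) {
    sub <- gm$gt[units == ulev[u], , drop = FALSE]
    called[u, ] <- 2L * colSums(!is.na(sub))
    derived[u, ] <- colSums(sub, na.rm = TRUE)
  }

  # private alleles: allele a (REF/ALT) at a site is private to the unit
  # where it is observed if no other unit carries it
  has_alt <- derived > 0
  has_ref <- (called - derived) > 0
  priv <- integer(length(ulev))
  for (u in seq_along(ulev)) {
    other_alt <- colSums(has_alt[-u, , drop = FALSE]) > 0
    other_ref <- colSums(has_ref[-u, , drop = FALSE]) > 0
    priv[u] <- sum(has_alt[u, ] & !other_alt) + sum(has_ref[u, ] & !other_ref)
  }

  rows <- lapply(seq_along(ulev), function(u) {
    n <- called[u, ]
    d <- derived[u, ]
    usable <- n >= 2L
    if (!any(usable)) {
      return(tibble::tibble(unit = ulev[u],
                            sites_recovered = sum(n > 0),
                            pct_polymorphic = NA_real_,
                            expected_heterozygosity = NA_real_,
                            nucleotide_diversity_pi = NA_real_,
                            private_alleles = priv[u]))
    }
    p <- d[usable] / n[usable]
    he <- 2 * p * (1 - p)
    corr <- n[usable] / (n[usable] - 1)
    tibble::tibble(
      unit = ulev[u],
      sites_recovered = sum(n > 0),
      pct_polymorphic = 100 * mean(p > 0 & p < 1),
      expected_heterozygosity = mean(he),
      nucleotide_diversity_pi = mean(corr * he),
      private_alleles = priv[u]
    )
  })
  dplyr::bind_rows(rows)
}

#' Mann-Whitney U test with midranks
#'
#' Rank-sum comparison of two samples using midranks for ties.  For a
#' combined sample size of at most `exact_max` the two-sided p-value is
#' computed by exact enumeration of all group assignments of the pooled
#' values; otherwise a normal approximation with the tie correction is used.
#'
#' @param x,y numeric samples.
#' @param exact_max largest combined size for exact enumeration.
#' @return A tibble with columns `U`, `p_two_sided` and `method`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))
#' @export
mann_whitney_u <- function(x, y, exact_max = 12) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0)
    stop("both samples must be non-empty", call. = FALSE)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  u_stat <- function(idx) {
    r <- rank(pooled)  # midranks
    sum(r[idx]) - length(idx) * (length(idx) + 1) / 2
  }
  U <- u_stat(seq_len(n1))
  mid <- n1 * n2 / 2
  if (N <= exact_max) {
    combos <- combn(N, n1)
    Us <- apply(combos, 2, u_stat)
    p <- mean(abs(Us - mid) >= abs(U - mid) - 1e-12)
    method <- "exact"
  } else {
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mid) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal"
  }
  tibble::tibble(U = U, p_two_sided = p, method = method)
}
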