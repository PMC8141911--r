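#' Missing-data filters for SFS construction
#'
#' Defaults mirror common RADseq practice: genotypes below 5x depth are set
#' missing and sites missing in more than half of the individuals are
#' dropped.
#'
#' @param max_missing_fraction maximum tolerated fraction of missing
#'   individuals per site, in `[0, 1]`.
#' @param min_depth minimum per-genotype depth; lower-depth calls are set
#'   missing.
#' @param one_snp_per_locus keep only the first SNP of each locus (linkage
#'   thinning).
#' @return An `sfs_filter_config` list.
#' @export
sfs_filter_config <- function(max_missing_fraction = 0.5, min_depth = 5,
                              one_snp_per_locus = FALSE) {
  stopifnot(max_missing_fraction >= 0, max_missing_fraction <= 1,
            min_depth >= 0)
  structure(list(max_missing_fraction = max_missing_fraction,
                 min_depth = as.integer(min_depth),
                 one_snp_per_locus = isTRUE(one_snp_per_locus)),
            class = "sfs_filter_config")
}

# apply depth + per-site missingness filters; returns filtered gt submatrix
# (individuals of the two pops only) plus site keep flags
filter_genotypes <- function(gm, pops, filters) {
  sel <- gm$pop %in% pops
  gt <- gm$gt[sel, , drop = FALSE]
  dp <- gm$depth[sel, , drop = FALSE]
  gt[dp < filters$min_depth] <- NA_integer_
  keep <- colMeans(is.na(gt)) <= filters$max_missing_fraction
  if (filters$one_snp_per_locus)
    keep <- keep & !duplicated(gm$sites$locus)
  list(gt = gt, pop = gm$pop[sel], keep = keep)
}

#' Build a folded joint SFS from genotypes
#'
#' Applies the depth and missing-data filters, computes per-site alternate
#' allele counts in the two populations, redistributes each site's
#' configuration onto the projected sample sizes by hypergeometric
#' expectation, and folds the result.  Sites with fewer called alleles than
#' the projection size in either population contribute nothing.
#'
#' @param gm a [genotype_matrix()].
#' @param pops character pair: the two population labels.
#' @param filters an [sfs_filter_config()].
#' @param projection haploid projection sizes `c(m1, m2)`, or `"auto"` to
#'   let [choose_projection()] pick them.
#' @return A folded `joint_sfs` of shape `(m1 + 1) x (m2 + 1)`.
#' @export
jsfs_from_genotypes <- function(gm, pops, filters = sfs_filter_config(),
                                projection = "auto") {
  stopifnot(inherits(gm, "genotype_matrix"), length(pops) == 2L)
  if (!all(pops %in% gm$pop))
    stop("both populations must be present in the genotype matrix",
         call. = FALSE)
  if (identical(projection, "auto"))
    projection <- choose_projection(gm, pops, filters)
  projection <- as.integer(projection)
  f <- filter_genotypes(gm, pops, filters)
  m1 <- projection[1L]; m2 <- projection[2L]
  max1 <- 2L * sum(f$pop == pops[1L])
  max2 <- 2L * sum(f$pop == pops[2L])
  if (m1 > max1 || m2 > max2)
    stop("projection larger than the available haploid sample sizes",
         call. = FALSE)
  counts <- matrix(0, m1 + 1L, m2 + 1L)
  in1 <- f$pop == pops[1L]; in2 <- f$pop == pops[2L]
  for (s in which(f$keep)) {
    g1 <- f$gt[in1, s]; g2 <- f$gt[in2, s]
    c1 <- 2L * sum(!is.na(g1)); c2 <- 2L * sum(!is.na(g2))
    if (c1 < m1 || c2 < m2) next
    d1 <- sum(g1, na.rm = TRUE); d2 <- sum(g2, na.rm = TRUE)
    w1 <- hyper_row(d1, c1, m1)
    w2 <- hyper_row(d2, c2, m2)
    counts <- counts + outer(w1, w2)
  }
  fold_jsfs(jsfs(counts, folded = FALSE))
}

# P(k derived of m | d derived of n), k = 0..m
hyper_row <- function(d, n, m) {
  k <- 0:m
  exp(lchoose(d, k) + lchoose(n - d, m - k) - lchoose(n, m))
}

#' Choose the SFS down-projection maximizing retained polymorphism
#'
#' Scans candidate haploid projection sizes for both populations and returns
#' the pair maximizing the expected number of segregating sites retained in
#' the projected joint spectrum (a site contributes its probability of
#' remaining polymorphic under hypergeometric subsampling; sites with fewer
#' called alleles than a candidate size contribute nothing to it).  Ties are
#' broken toward larger sizes.
#'
#' @inheritParams jsfs_from_genotypes
#' @return Integer pair `c(m1, m2)`.
#' @export
choose_projection <- function(gm, pops, filters = sfs_filter_config()) {
  stopifnot(inherits(gm, "genotype_matrix"), length(pops) == 2L)
  f <- filter_genotypes(gm, pops, filters)
  in1 <- f$pop == pops[1L]; in2 <- f$pop == pops[2L]
  if (!any(in1) || !any(in2))
    stop("both populations must be non-empty", call. = FALSE)
  sites <- which(f$keep)
  c1 <- 2L * colSums(!is.na(f$gt[in1, sites, drop = FALSE]))
  c2 <- 2L * colSums(!is.na(f$gt[in2, sites, drop = FALSE]))
  d1 <- colSums(f$gt[in1, sites, drop = FALSE], na.rm = TRUE)
  d2 <- colSums(f$gt[in2, sites, drop = FALSE], na.rm = TRUE)
  cand1 <- 2:max(2L * sum(in1), 2L)
  cand2 <- 2:max(2L * sum(in2), 2L)
  best <- c(2L, 2L); best_val <- -Inf
  for (m1 in cand1) for (m2 in cand2) {
    ok <- c1 >= m1 & c2 >= m2
    if (!any(ok)) next
    # polymorphic after projection: not (all-ancestral or all-derived jointly)
    pa <- exp(lchoose(c1[ok] - d1[ok], m1) - lchoose(c1[ok], m1)) *
      exp(lchoose(c2[ok] - d2[ok], m2) - lchoose(c2[ok], m2))
    pd <- exp(lchoose(d1[ok], m1) - lchoose(c1[ok], m1)) *
      exp(lchoose(d2[ok], m2) - lchoose(c2[ok], m2))
    val <- sum(1 - pa - pd)
    if (val > best_val + 1e-12 ||
        (abs(val - best_val) <= 1e-12 && sum(c(m1, m2)) > sum(best))) {
      best <- c(m1, m2); best_val <- val
    }
  }
  best
}
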