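# Shared fixtures and independent brute-force oracles.

# constant-size single-deme schedule (standard neutral coalescent)
neutral_schedule <- function() {
  refugia:::schedule(len = numeric(0), s1 = numeric(0), r1 = numeric(0),
                     s2 = numeric(0), r2 = numeric(0), m12 = numeric(0),
                     m21 = numeric(0), nuA = 1)
}

branch_jsfs_raw <- function(n1, n2, sch, reps, seed) {
  refugia:::cpp_branch_jsfs(n1, n2, sch$len, sch$s1, sch$r1, sch$s2, sch$r2,
                            sch$m12, sch$m21, sch$nuA, reps, seed)
}

coal_summaries_raw <- function(n1, n2, sch, reps, seed) {
  refugia:::cpp_coal_summaries(n1, n2, sch$len, sch$s1, sch$r1, sch$s2,
                               sch$r2, sch$m12, sch$m21, sch$nuA, reps, seed)
}

# Brute-force 1D hypergeometric projection by subset enumeration: all C(n, m)
# subsamples of n alleles of which d are derived.
enum_projection_1d <- function(d, n, m) {
  subsets <- utils::combn(n, m)
  derived <- seq_len(n) <= d
  k <- apply(subsets, 2, function(s) sum(derived[s]))
  tabulate(k + 1L, nbins = m + 1L) / ncol(subsets)
}

# Split a pooled derived count d among (n1, n2) alleles: multivariate
# hypergeometric mass over counts in the first subsample.
hyper_split <- function(d, n1, n2) {
  k <- 0:min(d, n1)
  p <- exp(lchoose(n1, k) + lchoose(n2, d - k) - lchoose(n1 + n2, d))
  out <- numeric(n1 + 1)
  out[k + 1] <- p
  out
}

# Brute-force fold of an unfolded matrix by minor-allele tallying.
brute_fold <- function(counts) {
  n1 <- nrow(counts) - 1L; n2 <- ncol(counts) - 1L
  out <- matrix(0, n1 + 1L, n2 + 1L)
  seen <- matrix(FALSE, n1 + 1L, n2 + 1L)
  freq <- function(i, j) {
    f <- 0
    if (n1 > 0) f <- f + i / n1
    if (n2 > 0) f <- f + j / n2
    f
  }
  for (i in 0:n1) for (j in 0:n2) {
    ci <- n1 - i; cj <- n2 - j
    f <- freq(i, j); fc <- freq(ci, cj)
    tgt <- if (f < fc) c(i, j)
      else if (f > fc) c(ci, cj)
      else if (i < ci || (i == ci && j <= cj)) c(i, j) else c(ci, cj)
    out[tgt[1] + 1L, tgt[2] + 1L] <- out[tgt[1] + 1L, tgt[2] + 1L] +
      counts[i + 1L, j + 1L]
    seen[tgt[1] + 1L, tgt[2] + 1L] <- TRUE
  }
  list(counts = out, kept = seen)
}

random_jsfs <- function(n1, n2, lambda = 5) {
  jsfs(matrix(rpois((n1 + 1) * (n2 + 1), lambda), n1 + 1, n2 + 1))
}

# small deterministic genotype fixture: two populations of diploids
toy_genotypes <- function() {
  gt <- rbind(
    c(0L, 1L, 2L, 0L, 1L),
    c(1L, 1L, 2L, 0L, 0L),
    c(0L, 0L, 1L, 0L, 2L),
    c(2L, 0L, 0L, 1L, 1L),
    c(1L, 0L, 0L, 2L, 0L),
    c(2L, 0L, 1L, 1L, 0L)
  )
  genotype_matrix(gt, pop = rep(c("A", "B"), each = 3),
                  sites = tibble::tibble(locus = paste0("L", c(1, 1, 2, 3, 3)),
                                         pos = c(5L, 9L, 2L, 4L, 8L)))
}
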