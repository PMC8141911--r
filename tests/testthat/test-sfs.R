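test_that("hypergeometric projection matches hand and enumeration oracles", {
  # identity projection
  x <- random_jsfs(4, 3)
  expect_equal(project_jsfs(x, c(4, 3))$counts, x$counts)

  # 1D: n = 4, single SNP with derived count 2, projected to m = 2
  cnt <- matrix(0, 5, 1); cnt[3, 1] <- 1
  pr <- project_jsfs(jsfs(cnt), c(2, 0))
  expect_equal(as.vector(pr$counts), c(1 / 6, 4 / 6, 1 / 6))

  # all 1D spectra up to n = 6 against subset enumeration
  for (n in 2:6) for (m in 2:n) for (d in 0:n) {
    cnt <- matrix(0, n + 1, 1); cnt[d + 1, 1] <- 1
    pr <- project_jsfs(jsfs(cnt), c(m, 0))
    expect_equal(as.vector(pr$counts), enum_projection_1d(d, n, m),
                 tolerance = 1e-12)
  }

  # projection larger than the source errors
  expect_error(project_jsfs(jsfs(matrix(0, 3, 3)), c(4, 2)), "larger")
})

test_that("projection conserves total mass to 1e-12 on random spectra", {
  set.seed(42)
  for (r in 1:100) {
    n1 <- sample(3:8, 1); n2 <- sample(2:8, 1)
    x <- random_jsfs(n1, n2)
    m1 <- sample(2:n1, 1); m2 <- sample(2:n2, 1)
    pr <- project_jsfs(x, c(m1, m2))
    expect_lt(abs(sum(pr$counts) - sum(x$counts)), 1e-12 * max(1, sum(x$counts)))
  }
})

test_that("folding combines complements, masks the redundant half, conserves mass", {
  # 1D n = 4: [0, 3, 2, 1, 0] -> [masked, 4, 2, masked, masked]
  f <- fold_jsfs(jsfs(matrix(c(0, 3, 2, 1, 0), ncol = 1)))
  expect_true(f$folded)
  expect_equal(f$counts[2, 1], 4)
  expect_equal(f$counts[3, 1], 2)
  expect_true(f$mask[1, 1] && f$mask[4, 1] && f$mask[5, 1])
  expect_false(f$mask[2, 1] || f$mask[3, 1])

  expect_error(fold_jsfs(f), "already folded")

  set.seed(7)
  for (r in 1:50) {
    n1 <- sample(2:7, 1); n2 <- sample(2:7, 1)
    x <- random_jsfs(n1, n2)
    f <- fold_jsfs(x)
    oracle <- brute_fold(x$counts)
    expect_equal(f$counts[!f$mask], oracle$counts[!f$mask])
    # mass conservation (corner mass excluded on both sides)
    inner <- x$counts
    inner[1, 1] <- 0; inner[n1 + 1, n2 + 1] <- 0
    expect_lt(abs(sum(f$counts[!f$mask]) - sum(inner)), 1e-12 * sum(x$counts))
  }

  # symmetric spectrum: folded cell = 2x unfolded except self-complementary
  sym <- matrix(2, 5, 3)
  fs <- fold_jsfs(jsfs(sym))
  keep <- which(!fs$mask, arr.ind = TRUE)
  for (k in seq_len(nrow(keep))) {
    i <- keep[k, 1] - 1L; j <- keep[k, 2] - 1L
    expected <- if (i == 4 - i && j == 2 - j) 2 else 4
    expect_equal(fs$counts[keep[k, 1], keep[k, 2]], expected)
  }
})

test_that("projection-then-fold agrees with the brute-force minor-allele tally", {
  set.seed(19)
  for (r in 1:20) {
    x <- random_jsfs(6, 5)
    pf <- fold_jsfs(project_jsfs(x, c(4, 3)))
    # oracle: project by enumeration weights, then brute-fold
    W1 <- refugia:::projection_weights(6, 4)
    W2 <- refugia:::projection_weights(5, 3)
    proj <- t(W1) %*% x$counts %*% W2
    oracle <- brute_fold(proj)
    expect_equal(pf$counts[!pf$mask], oracle$counts[!pf$mask],
                 tolerance = 1e-12)
  }
})

test_that("folded spectrum of neutral data follows 1/i + 1/(n-i)", {
  n <- 10
  b <- branch_jsfs_raw(n, 0, neutral_schedule(), 200000, 99)
  f <- fold_jsfs(jsfs(b))
  eta <- f$counts[2:(n / 2 + 1), 1]
  expected <- 2 / (1:(n / 2)) + 2 / (n - 1:(n / 2))
  expected[n / 2] <- 2 / (n / 2)  # self-complementary class kept once
  expect_equal(eta / eta[1], expected / expected[1], tolerance = 0.03)
})

test_that("multinomial log-likelihood matches its worked example and contracts", {
  one_col <- function(v) jsfs(matrix(v, ncol = 1),
                              mask = matrix(FALSE, length(v), 1))
  d <- one_col(c(2, 1))
  expect_equal(loglik_multinom(d, d), (2 * log(2) - 2 - log(2)) + (0 - 1 - 0),
               tolerance = 1e-10)
  expect_equal(round(loglik_multinom(d, d), 4), -2.3069)

  # invariance to model scale
  m2 <- one_col(c(2, 1) * 37.5)
  m2$folded <- d$folded
  expect_equal(loglik_multinom(d, m2), loglik_multinom(d, d))

  # all-zero data
  z <- one_col(c(0, 0))
  expect_equal(loglik_multinom(z, d), 0)

  # model zero where data positive
  m0 <- one_col(c(0, 1))
  expect_identical(loglik_multinom(d, m0), -Inf)

  # shape/mask mismatches error
  expect_error(loglik_multinom(d, one_col(c(1, 2, 3))), "shape")
  dm <- one_col(c(2, 1)); dm$mask[1, 1] <- TRUE
  expect_error(loglik_multinom(d, dm), "mask")

  # self-consistency: the data spectrum is its own best model
  set.seed(31)
  base <- fold_jsfs(random_jsfs(6, 6))
  ll_self <- loglik_multinom(base, base)
  for (r in 1:25) {
    pert <- base
    pert$counts[!pert$mask] <- pert$counts[!pert$mask] *
      exp(runif(sum(!pert$mask), -0.5, 0.5))
    expect_lte(ll_self, loglik_multinom(base, base))
    expect_gte(ll_self, loglik_multinom(base, pert))
  }
})

test_that("optimal theta scaling is the ratio of unmasked sums", {
  a <- jsfs(matrix(c(0, 60, 40, 0), 2, 2))
  b <- jsfs(matrix(c(0, 30, 20, 0), 2, 2))
  expect_equal(optimal_scaling_theta(a, b), 2)
  expect_equal(optimal_scaling_theta(a, a), 1)
  set.seed(5)
  for (r in 1:100) {
    x <- random_jsfs(5, 4); y <- random_jsfs(5, 4)
    y$counts <- y$counts + 0.5
    expect_equal(optimal_scaling_theta(x, y),
                 sum(x$counts[!x$mask]) / sum(y$counts[!y$mask]))
  }
})

test_that("SFS construction applies depth, missingness and projection rules", {
  # 1 site: pop1 one het (1 of 2), pop2 one ref-homozygote (0 of 2)
  gm <- genotype_matrix(matrix(c(1L, 0L), nrow = 2), pop = c("A", "B"))
  s <- jsfs_from_genotypes(gm, c("A", "B"), projection = c(2, 2))
  expect_true(s$folded)
  expect_equal(s$counts[2, 1], 1)
  expect_equal(sum(s$counts[!s$mask]), 1)

  # a site missing in 3 of 5 individuals (60% > 50%) contributes nothing
  gt <- matrix(c(1L, NA, NA, NA, 0L,   # site 1: 60% missing
                 1L, 0L, 0L, 0L, 0L),  # site 2: complete
               nrow = 5)
  gm2 <- genotype_matrix(gt, pop = c("A", "A", "A", "B", "B"))
  s2 <- jsfs_from_genotypes(gm2, c("A", "B"), projection = c(2, 2))
  expect_equal(sum(s2$counts), 1)  # only the complete site (all-cell mass)

  # depth filter: low-depth calls are set missing first
  dp <- matrix(10L, 5, 2); dp[2, 2] <- 3L
  gm3 <- genotype_matrix(gt, pop = c("A", "A", "A", "B", "B"), depth = dp)
  s3 <- jsfs_from_genotypes(gm3, c("A", "B"),
                            filters = sfs_filter_config(min_depth = 5),
                            projection = c(2, 2))
  # site 2 loses individual 2 but still projects from 4 called alleles in A
  expect_equal(sum(s3$counts), 1)

  # mass conservation on a larger fixture, brute tally oracle
  cfg <- scenario_config("vicariance",
                         params = list(nuA = 1, nu1 = 1, nu2 = 1, T = 0.3,
                                       s = 0.5),
                         n1 = 8, n2 = 8, n_loci = 60, theta_per_site = 0.008,
                         seed = 33)
  gm4 <- simulate_demography(cfg)
  s4 <- jsfs_from_genotypes(gm4, c("pop1", "pop2"), projection = c(8, 8))
  # with no missing data and full-size projection, every polymorphic site
  # contributes one unit unless projection fixes it (impossible here)
  expect_equal(sum(s4$counts[!s4$mask]), n_sites(gm4))

  expect_error(jsfs_from_genotypes(gm, c("A", "B"), projection = c(4, 2)),
               "projection")
  expect_error(jsfs_from_genotypes(gm, c("A", "C"), projection = c(2, 2)),
               "population")
})

test_that("projection choice maximizes expected retained polymorphism", {
  # no missing data: full haploid sizes
  gm <- toy_genotypes()
  expect_identical(choose_projection(gm, c("A", "B")), c(6L, 6L))
  expect_identical(choose_projection(gm, c("A", "B")),
                   choose_projection(gm, c("A", "B")))

  # one SNP callable in only 1 of 3 pop-A individuals: projecting A to 2
  # keeps both SNPs, the full size keeps one
  gt <- matrix(c(1L, NA, NA, 0L, 0L,
                 1L, 0L, 0L, 0L, 0L),
               nrow = 5)
  gm2 <- genotype_matrix(gt, pop = c("A", "A", "A", "B", "B"))
  filters <- sfs_filter_config(max_missing_fraction = 0.5)
  pick <- choose_projection(gm2, c("A", "B"), filters)
  expect_identical(pick[1], 2L)
  # exhaustive check: expected segregating sites higher at (2, 4) than (6, 4)
  s_small <- jsfs_from_genotypes(gm2, c("A", "B"), filters, c(2, 4))
  s_full <- jsfs_from_genotypes(gm2, c("A", "B"), filters, c(6, 4))
  seg <- function(s) {
    poly <- s$counts
    sum(poly[!s$mask])
  }
  expect_gt(seg(s_small), seg(s_full))
})

test_that("the flat-text SFS format round-trips bit-exactly", {
  set.seed(3)
  x <- fold_jsfs(random_jsfs(5, 7))
  p <- tempfile(fileext = ".sfs")
  write_sfs(x, p)
  y <- read_sfs(p)
  expect_identical(y$counts, x$counts)
  expect_identical(y$mask, x$mask)
  expect_identical(y$folded, x$folded)
  # fractional mass round-trips at full double precision
  z <- project_jsfs(random_jsfs(6, 4), c(3, 2))
  write_sfs(z, p)
  expect_equal(read_sfs(p)$counts, z$counts, tolerance = 1e-15)
})
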