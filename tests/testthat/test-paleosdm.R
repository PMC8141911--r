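# helpers to build monthly series grids
make_series <- function(nr, nc, years, fun, cellsize = 1, start_year = 1901) {
  n_years <- length(years)
  arr <- array(0, c(nr, nc, 12 * n_years))
  for (y in seq_len(n_years)) for (m in 1:12)
    arr[, , (y - 1) * 12 + m] <- fun(years[y], m)
  climate_grid(arr, cellsize = cellsize, kind = "t_mean",
               start_year = start_year)
}

test_that("window means average the right months", {
  const <- make_series(3, 4, 1901:1960, function(y, m) 5)
  wm <- window_mean(const, c(1920, 1949))
  expect_true(all(wm$values == 5))

  alt <- make_series(2, 2, 1901:1910, function(y, m) if (y %% 2 == 0) 0 else 2)
  expect_true(all(window_mean(alt, c(1901, 1910))$values == 1))

  set.seed(6)
  rnd <- make_series(2, 3, 1901:1930,
                     function(y, m) matrix(rnorm(6, mean = m), 2, 3))
  wm2 <- window_mean(rnd, c(1905, 1914))
  sel <- 1905:1914 - 1900
  for (m in 1:12) {
    idx <- (sel - 1) * 12 + m
    expect_equal(wm2$values[, , m],
                 apply(rnd$values[, , idx], c(1, 2), mean))
  }
  expect_error(window_mean(rnd, c(1890, 1920)), "outside")
})

test_that("deltas are differences for temperature and ratios for precipitation", {
  a <- climate_grid(matrix(10, 3, 3))
  expect_true(all(compute_deltas(a, a, "temperature")$values == 0))
  b <- climate_grid(matrix(5, 3, 3))
  expect_true(all(compute_deltas(b, a, "temperature")$values == -5))

  p <- climate_grid(matrix(100, 3, 3), kind = "precip")
  expect_true(all(compute_deltas(p, p, "precipitation")$values == 1))

  pz <- climate_grid(matrix(c(0, 50, 100, 0, 25, 10, 5, 1, 2), 3, 3),
                     kind = "precip")
  d <- compute_deltas(p, pz, "precipitation")
  expect_equal(d$values[1, 1, 1], 1)  # zero reference flagged to no-change
  expect_equal(length(attr(d, "flagged_cells")), 2L)
  expect_equal(d$values[2, 1, 1], 2)

  set.seed(9)
  h <- climate_grid(matrix(rnorm(9, 10), 3, 3))
  r <- climate_grid(matrix(rnorm(9, 12), 3, 3))
  expect_equal(compute_deltas(h, r, "temperature")$values,
               h$values - r$values)
  expect_error(compute_deltas(h, climate_grid(matrix(1, 2, 2)), "temperature"),
               "co-registered")
})

test_that("thin plate splines reproduce nodes and affine surfaces", {
  cg <- climate_grid(matrix(7.5, 4, 4), cellsize = 4)
  fine <- interpolate_field(cg, 1)
  expect_equal(dim(fine$values)[1:2], c(16L, 16L))
  expect_true(all(abs(fine$values - 7.5) < 1e-8))

  # affine field a + b x + c y is reproduced exactly
  cc <- refugia:::grid_centers(cg)
  z <- outer(cc$y, cc$x, function(y, x) 2 + 0.3 * x - 0.7 * y)
  ag <- climate_grid(z, cellsize = 4)
  fa <- interpolate_field(ag, 1)
  fc <- refugia:::grid_centers(fa)
  expected <- outer(fc$y, fc$x, function(y, x) 2 + 0.3 * x - 0.7 * y)
  expect_true(max(abs(fa$values[, , 1] - expected)) < 1e-7)

  # interpolation is exact at the nodes
  set.seed(10)
  zr <- matrix(rnorm(16), 4, 4)
  rg <- climate_grid(zr, cellsize = 4)
  back <- interpolate_field(rg, 4)
  expect_true(max(abs(back$values[, , 1] - zr)) < 1e-8)

  expect_error(interpolate_field(climate_grid(matrix(NA_real_, 3, 3)), 1),
               "non-missing")
})

test_that("delta application adds, multiplies and clamps correctly", {
  ref <- climate_grid(matrix(10, 3, 3))
  z0 <- climate_grid(matrix(0, 3, 3))
  expect_equal(apply_deltas(ref, z0, "temperature")$values, ref$values)
  z1 <- climate_grid(matrix(1, 3, 3))
  expect_equal(apply_deltas(ref, z1, "precipitation")$values, ref$values)
  m5 <- climate_grid(matrix(-5, 3, 3))
  expect_true(all(apply_deltas(ref, m5, "temperature")$values == 5))
  neg <- climate_grid(matrix(-0.5, 3, 3))
  clamped <- apply_deltas(ref, neg, "precipitation")
  expect_true(all(clamped$values == 0))
  expect_equal(length(attr(clamped, "flagged_cells")), 9L)
})

test_that("the two-step downscaling chain is exact under stationarity", {
  # stationary series at all three resolutions: output == fine climatology
  paleo <- make_series(2, 2, 1,  # placeholder, rebuilt below
                       function(y, m) 0)
  paleo <- make_series(2, 2, 1851:1980, function(y, m) 10 + m, cellsize = 8,
                       start_year = 1851)
  mid <- make_series(4, 4, 1901:2016, function(y, m) 12 + m, cellsize = 4,
                     start_year = 1901)
  fine_vals <- array(rep(outer(1:8, 1:8, function(a, b) 15 + a * 0.1), 12),
                     c(8, 8, 12))
  for (m in 1:12) fine_vals[, , m] <- fine_vals[, , m] + m
  fine <- climate_grid(fine_vals, cellsize = 1)
  periods <- list(historic = c(1860, 1889), ref1 = c(1950, 1980),
                  ref2 = c(1979, 2013))
  out <- downscale_two_step(paleo, mid, fine, periods, "temperature")
  expect_true(max(abs(out$values - fine$values)) < 1e-8)

  # a spatially constant historic offset of -3 propagates unchanged
  paleo2 <- make_series(2, 2, 1851:1980,
                        function(y, m) if (y < 1900) 10 + m - 3 else 10 + m,
                        cellsize = 8, start_year = 1851)
  out2 <- downscale_two_step(paleo2, mid, fine, periods, "temperature")
  expect_true(max(abs(out2$values - (fine$values - 3))) < 1e-8)

  # determinism
  out3 <- downscale_two_step(paleo2, mid, fine, periods, "temperature")
  expect_identical(out2$values, out3$values)

  expect_error(downscale_two_step(paleo, mid, fine,
                                  list(historic = c(1700, 1729),
                                       ref1 = c(1950, 1980),
                                       ref2 = c(1979, 2013)), "temperature"),
               "outside")
  expect_error(downscale_two_step(mid, mid, fine, periods, "temperature"),
               "ordered")
})

test_that("bioclim variables follow their conventions", {
  const_t <- climate_grid(array(10, c(2, 2, 12)))
  const_p <- climate_grid(array(100, c(2, 2, 12)), kind = "precip")
  bio <- derive_bioclim(const_t, const_p)
  expect_true(all(bio$bio1$values == 10))
  expect_true(all(bio$bio4$values == 0))
  expect_true(all(bio$bio12$values == 1200))
  expect_true(all(bio$bio15$values == 0))

  # alternating 50/150 mm: bio12 = 1200, bio15 = 100 * sd / mean
  alt <- array(rep(c(50, 150), each = 4, times = 6), c(2, 2, 12))
  altp <- climate_grid(alt, kind = "precip")
  bio2 <- derive_bioclim(const_t, altp)
  expect_true(all(bio2$bio12$values == 1200))
  hand_sd <- sd(rep(c(50, 150), 6))
  expect_equal(bio2$bio15$values[1, 1, 1], 100 * hand_sd / 100)

  # month permutation leaves all four summaries unchanged
  set.seed(12)
  tv <- array(rnorm(2 * 2 * 12, 8, 4), c(2, 2, 12))
  pv <- array(rexp(2 * 2 * 12, 1 / 80), c(2, 2, 12))
  perm <- sample(12)
  b_a <- derive_bioclim(climate_grid(tv), climate_grid(pv, kind = "precip"))
  b_b <- derive_bioclim(climate_grid(tv[, , perm]),
                        climate_grid(pv[, , perm], kind = "precip"))
  for (nm in names(b_a))
    expect_equal(b_a[[nm]]$values, b_b[[nm]]$values)

  # zero-precipitation cells flagged missing in bio15
  pz <- array(0, c(2, 2, 12))
  bz <- derive_bioclim(const_t, climate_grid(pz, kind = "precip"))
  expect_true(all(is.na(bz$bio15$values)))
})

test_that("roughness is the population SD of enclosed fine elevations", {
  flat <- climate_grid(matrix(100, 10, 10), cellsize = 1, kind = "elevation")
  r0 <- topo_roughness(flat, 5)
  expect_true(all(r0$values == 0))

  # half 0 / half 10 in each block: population SD = 5
  z <- matrix(rep(c(0, 10), each = 5, times = 10), 10, 10)
  rh <- topo_roughness(climate_grid(z, cellsize = 1, kind = "elevation"), 10)
  expect_equal(rh$values[1, 1, 1], 5)

  set.seed(13)
  zr <- matrix(rnorm(64, 500, 50), 8, 8)
  rr <- topo_roughness(climate_grid(zr, cellsize = 1, kind = "elevation"), 4)
  for (i in 1:2) for (j in 1:2) {
    blk <- zr[(i - 1) * 4 + 1:4, (j - 1) * 4 + 1:4]
    expect_equal(rr$values[i, j, 1], sqrt(mean((blk - mean(blk))^2)))
  }

  # partial edge blocks flagged
  rp <- topo_roughness(climate_grid(matrix(1, 5, 5), cellsize = 1,
                                    kind = "elevation"), 2)
  expect_gt(length(attr(rp, "partial_cells")), 0)

  expect_error(topo_roughness(flat, 2.5), "divide")
})

test_that("collinearity screening flags matching and opposing layers", {
  set.seed(14)
  a <- climate_grid(matrix(rnorm(100), 10, 10))
  b <- climate_grid(matrix(rnorm(100), 10, 10))
  rep_a <- climate_grid(a$values[, , 1])
  neg_a <- climate_grid(-a$values[, , 1])
  rpt <- screen_collinearity(list(a = a, b = b, same = rep_a, opp = neg_a))
  get <- function(l1, l2) rpt[rpt$layer1 == l1 & rpt$layer2 == l2, ]
  expect_equal(get("a", "same")$r, 1)
  expect_true(get("a", "same")$flagged)
  expect_equal(get("a", "opp")$r, -1)
  expect_true(get("a", "opp")$flagged)
  expect_false(get("a", "b")$flagged)
  # constant layer: undefined correlation, flagged
  cst <- climate_grid(matrix(3, 10, 10))
  rpt2 <- screen_collinearity(list(a = a, c = cst))
  expect_true(is.na(rpt2$r[1]) && rpt2$flagged[1])
})

test_that("pseudo-absence draws avoid exclusions and are uniform", {
  dom <- matrix(1, 20, 20)
  excl <- matrix(0, 20, 20); excl[1:10, ] <- 1
  pts <- draw_pseudoabsences(dom, 50, list(excl), seed = 3)
  expect_equal(nrow(pts), 50L)
  expect_true(all(pts$row > 10))
  expect_false(any(duplicated(paste(pts$row, pts$col))))
  expect_identical(pts, draw_pseudoabsences(dom, 50, list(excl), seed = 3))

  # domain minus exclusions leaving exactly n cells returns those cells
  excl_all <- matrix(1, 20, 20); excl_all[3, c(4, 9, 17)] <- 0
  pts2 <- draw_pseudoabsences(dom, 3, list(excl_all), seed = 1)
  expect_setequal(pts2$col, c(4L, 9L, 17L))
  expect_true(all(pts2$row == 3L))

  expect_error(draw_pseudoabsences(dom, 500, list(excl_all)), "available")

  # uniformity over strata (chi-square on 4 quadrants)
  big <- draw_pseudoabsences(matrix(1, 100, 100), 1e4, seed = 7)
  strata <- 2 * (big$row > 50) + (big$col > 50)
  cs <- suppressWarnings(stats::chisq.test(table(strata)))
  expect_gt(cs$p.value, 0.001)
})

test_that("the pseudo-absence GLM recovers known structure", {
  # intercept-only: logit of prevalence
  pres <- tibble::tibble(row = rep(1, 30), col = rep(1, 30))
  abs <- tibble::tibble(row = rep(1, 70), col = rep(1, 70))
  m0 <- fit_occurrence_glm(pres, abs, layers = list())
  expect_equal(unname(coef(m0$fit)[1]), log(30 / 70), tolerance = 1e-6)
  expect_equal(round(unname(coef(m0$fit)[1]), 4), -0.8473)

  # quadratic-logit recovery within 3 SE at n = 5000
  set.seed(15)
  n <- 5000
  x1 <- rnorm(n); x2 <- rnorm(n)
  eta <- -0.5 + 1.2 * x1 - 0.8 * x1^2 + 0.6 * x2 - 0.3 * x2^2
  y <- rbinom(n, 1, plogis(eta))
  df <- tibble::tibble(v1 = x1, v2 = x2)
  mfit <- fit_occurrence_glm(df[y == 1, ], df[y == 0, ],
                             layers = list(v1 = climate_grid(matrix(0, 1, 1)),
                                           v2 = climate_grid(matrix(0, 1, 1))))
  # predictors are standardized internally; compare on the response scale
  est <- summary(mfit$fit)$coefficients
  truth_fit <- glm(y ~ x1 + I(x1^2) + x2 + I(x2^2), family = binomial())
  p_ours <- predict(mfit, df)
  p_direct <- unname(predict(truth_fit, type = "response"))
  expect_equal(p_ours, p_direct, tolerance = 1e-6)
  expect_true(all(p_ours >= 0 & p_ours <= 1))
  true_beta <- c(-0.5, 1.2, -0.8, 0.6, -0.3)
  expect_true(all(abs(coef(truth_fit) - c(true_beta)) /
                    summary(truth_fit)$coefficients[, 2] < 3 + 1e-9))

  # separation flagged
  sep <- tibble::tibble(v1 = c(rep(5, 20), rep(-5, 20)),
                        v2 = rnorm(40))
  msep <- fit_occurrence_glm(sep[1:20, ], sep[21:40, ],
                             layers = list(v1 = climate_grid(matrix(0, 1, 1)),
                                           v2 = climate_grid(matrix(0, 1, 1))))
  expect_true(msep$separated)
})

test_that("refugial augmentation adds one historic presence per area", {
  set.seed(16)
  nr <- 30; nc <- 30
  mk <- function(m) climate_grid(m, cellsize = 1)
  cur <- list(bio1 = mk(matrix(rnorm(nr * nc, 10, 3), nr, nc)),
              bio12 = mk(matrix(rnorm(nr * nc, 800, 150), nr, nc)))
  hist <- list(bio1 = mk(cur$bio1$values[, , 1] - 6),
               bio12 = mk(cur$bio12$values[, , 1] * 0.7))
  # presences where bio1 is high
  ok <- which(cur$bio1$values[, , 1] > 12, arr.ind = TRUE)
  pres <- tibble::tibble(row = ok[1:25, 1], col = ok[1:25, 2])
  abs0 <- draw_pseudoabsences(matrix(1, nr, nc), 200, seed = 5)
  m <- fit_occurrence_glm(pres, abs0, cur, seed = 5)

  ref1 <- matrix(0, nr, nc); ref1[1:5, 1:5] <- 1
  ref2 <- matrix(0, nr, nc); ref2[25:30, 25:30] <- 1
  aug <- augment_with_refugia(m, list(ref1, ref2), hist, cur,
                              domain_mask = matrix(1, nr, nc),
                              n_each = 100, seed = 9)
  expect_equal(nrow(aug$refugial_presences), 2L)
  expect_equal(aug$n_presence, 25L + 2L)
  # the appended climates are the per-area argmax under the pre-refit model
  v1 <- extract_layer_values(hist, tibble::tibble(
    row = which(ref1 == 1, arr.ind = TRUE)[, 1],
    col = which(ref1 == 1, arr.ind = TRUE)[, 2]))
  best1 <- v1[which.max(predict(m, v1)), ]
  expect_equal(aug$refugial_presences$bio1[1], best1$bio1)

  # an area with a single uniform climate is appended exactly once
  ref_u <- matrix(0, nr, nc); ref_u[10, 10] <- 1
  aug2 <- augment_with_refugia(m, list(ref_u), hist, cur,
                               domain_mask = matrix(1, nr, nc),
                               n_each = 50, seed = 11)
  expect_equal(nrow(aug2$refugial_presences), 1L)
  expect_equal(aug2$n_presence, 26L)

  # predicted probability at the appended climate does not collapse:
  # it is at least the probability of the refit model's own absences' median
  p_added <- predict(aug, aug$refugial_presences)
  expect_true(all(p_added >= 0 & p_added <= 1))

  expect_error(augment_with_refugia(m, list(matrix(0, nr, nc)), hist, cur,
                                    domain_mask = matrix(1, nr, nc)),
               "empty")
})
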