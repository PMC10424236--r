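# Histogramming, the WHAM solver, referencing, overlap diagnostics and
# bootstrap uncertainties.

toy_record <- function(center, k, samples) {
  window_record(umbrella_window(center, k), samples)
}

test_that("histogramming is left-closed right-open and conserves counts", {
  rec <- toy_record(2.1, 100, c(2.05, 2.05, 2.15))
  h <- histogram_window(rec, bin_edges = c(2.0, 2.1, 2.2))
  expect_equal(h$counts, c(2L, 1L))
  expect_equal(h$n_total, 3L)

  # boundary sample exactly on an interior edge goes right
  h2 <- histogram_window(toy_record(2.1, 100, 2.1), c(2.0, 2.1, 2.2))
  expect_equal(h2$counts, c(0L, 1L))

  expect_error(window_record(umbrella_window(2.1, 100), numeric(0)),
               "nonempty")
  expect_error(histogram_window(toy_record(2.1, 100, 2.5), c(2.0, 2.2)),
               "outside")
})

test_that("WHAM reduces to normalisation for near-zero bias and is duplication invariant", {
  set.seed(11)
  x <- runif(5000, 1, 3)
  rec <- toy_record(2, 1e-9, x)
  edges <- seq(1, 3, by = 0.1)
  h <- histogram_window(rec, edges)
  sol <- solve_wham(list(h), temperature = 300)
  expect_equal(sol$f, 0)
  expect_equal(sol$density, h$counts / sum(h$counts), tolerance = 1e-6)

  # duplicating a window changes nothing
  sol2 <- solve_wham(list(h, h), temperature = 300)
  expect_equal(sol2$density, sol$density, tolerance = 1e-9)
})

test_that("WHAM recovers a known harmonic free-energy profile within 0.1 kT", {
  kbt <- kT(300)
  a <- 40; x0 <- 5
  records <- harmonic_toy_records(a, x0, k = 200, centers = seq(4, 6, 0.1),
                                  n_per_window = 5e4, seed = 42)
  edges <- seq(3.5, 6.5, by = 0.02)
  prof <- pmf_from_records(records, edges, reference_r = 5.0)
  hists <- lapply(records, histogram_window, edges)
  tot <- Reduce(`+`, lapply(hists, function(h) h$counts))
  expected <- 0.5 * a * (prof$bin_centers - x0)^2
  ref <- which.min(abs(prof$bin_centers - 5.0))
  expected <- expected - expected[ref]
  ok <- tot >= 400 & is.finite(prof$v_eff)
  expect_gt(sum(ok), 50)
  expect_lt(max(abs(prof$v_eff - expected)[ok]) / kbt, 0.1)
})

test_that("single unbiased window equals direct Boltzmann inversion bin-by-bin", {
  set.seed(4)
  x <- rnorm(2e4, 2.5, 0.15)
  rec <- toy_record(2.5, 1e-9, x)
  edges <- seq(1.7, 3.3, by = 0.05)
  prof <- pmf_from_records(list(rec), edges, reference_r = 2.5)
  h <- histogram_window(rec, edges)
  kbt <- kT(300)
  direct <- ifelse(h$counts > 0, -kbt * log(h$counts / h$n_total), NA)
  ref <- which.min(abs(prof$bin_centers - 2.5))
  direct <- direct - direct[ref]
  expect_equal(prof$v_eff, direct, tolerance = 1e-6)
})

test_that("referencing, normalisation invariance and error handling of the PMF", {
  centers <- seq(1, 2, by = 0.1)
  uni <- rep(1, length(centers))
  p <- pmf_from_density(uni, centers, reference_r = 1.5)
  expect_true(all(p$v_eff == 0))
  # density ratio e between bins -> difference of exactly kT
  d <- c(1, exp(1))
  p2 <- pmf_from_density(d, c(1.0, 1.1), reference_r = 1.0)
  expect_equal(p2$v_eff[2], -kT(300), tolerance = 1e-12)
  # rescaling the density is irrelevant
  p3 <- pmf_from_density(37.5 * d, c(1.0, 1.1), reference_r = 1.0)
  expect_equal(p3$v_eff, p2$v_eff, tolerance = 1e-12)
  # empty reference bin
  expect_error(pmf_from_density(c(1, 0), c(1.0, 7.0), reference_r = 7.0),
               "reference bin")
  # gauge: first window free energy pinned to zero
  run <- get_two_bead_run()
  sol <- attr(pmf_from_records(run$records, run$edges,
                               reference_r = run$cfg$wham$reference_r),
              "wham")
  expect_equal(sol$f[1], 0)
})

test_that("zero-overlap window sets are rejected with the gap named", {
  r1 <- toy_record(1.0, 500, rnorm(200, 1.0, 0.02))
  r2 <- toy_record(2.0, 500, rnorm(200, 2.0, 0.02))
  edges <- seq(0.5, 2.5, 0.05)
  expect_error(
    solve_wham(lapply(list(r1, r2), histogram_window, edges)),
    "overlap")
})

test_that("overlap diagnostic matches hand-enumerated cases", {
  edges <- c(0, 1, 2)
  ha <- histogram_window(toy_record(0.5, 10, c(0.5, 1.5)), edges)
  hb <- histogram_window(toy_record(1.5, 10, c(0.5, 1.5)), edges)
  expect_equal(overlap_diagnostic(list(ha, hb))$overlap, 1.0)

  edges3 <- c(0, 1, 2, 3)
  h1 <- histogram_window(toy_record(0.5, 10, c(0.5, 1.5)), edges3)  # bins 1,2
  h2 <- histogram_window(toy_record(1.5, 10, c(1.5, 2.5)), edges3)  # bins 2,3
  expect_equal(overlap_diagnostic(list(h1, h2))$overlap, 0.5)

  hd1 <- histogram_window(toy_record(0.5, 10, c(0.2, 0.4)), edges3)
  hd2 <- histogram_window(toy_record(2.5, 10, c(2.2, 2.6)), edges3)
  od <- overlap_diagnostic(list(hd1, hd2))
  expect_equal(od$overlap, 0.0)
  expect_true(od$flagged)
})

test_that("bootstrap errors are zero for degenerate replicates and reproducible", {
  records <- harmonic_toy_records(40, 5, 200, seq(4.6, 5.4, 0.2), 2000,
                                  seed = 7)
  edges <- seq(4.3, 5.7, 0.05)
  b0 <- bootstrap_pmf(records, n_boot = 3, seed = 1, bin_edges = edges,
                      reference_r = 5.0, resample = FALSE)
  expect_true(all(b0$stderr[is.finite(b0$v_eff)] == 0))

  b1 <- bootstrap_pmf(records, n_boot = 8, seed = 5, bin_edges = edges,
                      reference_r = 5.0)
  b2 <- bootstrap_pmf(records, n_boot = 8, seed = 5, bin_edges = edges,
                      reference_r = 5.0)
  expect_identical(b1$stderr, b2$stderr)
  expect_true(any(b1$stderr > 0, na.rm = TRUE))
})

test_that("bootstrap errors shrink as 1/sqrt(n) on the harmonic toy", {
  edges <- seq(4.3, 5.7, 0.05)
  se_of <- function(n, seed) {
    recs <- harmonic_toy_records(40, 5, 200, seq(4.6, 5.4, 0.2), n, seed)
    b <- bootstrap_pmf(recs, n_boot = 25, seed = 17, bin_edges = edges,
                       reference_r = 5.0)
    stats::median(b$stderr[is.finite(b$v_eff) & b$stderr > 0], na.rm = TRUE)
  }
  ratio <- se_of(1000, 3) / se_of(4000, 3)
  expect_gt(ratio, 1.4)   # ideal factor 2 within Monte-Carlo slack
  expect_lt(ratio, 2.9)
})

test_that("biased mean restoring force matches the PMF slope per window", {
  # umbrella-integration identity: dA/dr at the window's sample mean equals
  # k (c - <r>); A here includes the radial-measure term, as does the
  # analytic expectation for the Debye-Hueckel pair
  run <- get_two_bead_run()
  ff <- run$ff
  edge <- run$cfg$system$box_edge_nm
  dAdr <- function(r) {
    h <- 1e-5
    (two_bead_expected_pmf(r + h, -2, -2, ff, edge, 2.8) -
     two_bead_expected_pmf(r - h, -2, -2, ff, edge, 2.8)) / (2 * h)
  }
  devs <- vapply(run$records, function(rec) {
    rbar <- mean(rec$rc_series)
    f_rest <- rec$window$force_k * (rec$window$center - rbar)
    se <- rec$window$force_k * stats::sd(rec$rc_series) /
      sqrt(length(rec$rc_series) / 20)  # crude autocorrelation allowance
    (f_rest - dAdr(rbar)) / se
  }, 0)
  # per-window agreement within error bars (|z| < 4), no systematic bias
  expect_lt(max(abs(devs)), 4)
  expect_lt(abs(mean(devs)), 1.5)
})
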