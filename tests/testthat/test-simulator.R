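# Reaction coordinate, bias, schedule, energy function and Metropolis
# sampler.

test_that("com_separation is the centroid distance and is translation invariant", {
  a <- single_bead(c(1, 1, 1))
  b <- single_bead(c(1, 1, 1))
  st <- make_state(a, b, edge = 20)
  expect_equal(com_separation(st), 0)

  b2 <- single_bead(c(4, 5, 1))  # offset (3, 4, 0) from a
  st2 <- make_state(a, b2, edge = 20)
  expect_equal(com_separation(st2), 5.0)

  shift <- c(2.5, -1.25, 3)
  st3 <- st2
  st3$molecule_a$positions <- st2$molecule_a$positions +
    matrix(shift, 1, 3, byrow = TRUE)
  st3$molecule_b$positions <- st2$molecule_b$positions +
    matrix(shift, 1, 3, byrow = TRUE)
  expect_equal(com_separation(st3), com_separation(st2), tolerance = 1e-12)
})

test_that("bias energy is harmonic with the production force constant", {
  w <- umbrella_window(3.0, 5000)
  expect_equal(bias_energy(w, 3.0), 0)
  expect_equal(bias_energy(w, 3.1), 25)   # 0.5 * 5000 * 0.1^2
  expect_equal(bias_energy(w, 2.9), 25)
  expect_equal(bias_energy(w, 3.2) / bias_energy(w, 3.1), 4)
  expect_error(umbrella_window(-1), "center")
  expect_error(umbrella_window(2, 0), "force_k")
})

test_that("window schedules cover the requested range uniformly", {
  s <- make_schedule(2.0, 7.0, 0.1, 5000)
  centers <- vapply(s$windows, function(w) w$center, 0)
  expect_length(centers, 51)
  expect_equal(centers[1], 2.0)
  expect_equal(centers[51], 7.0)
  expect_true(all(abs(diff(centers) - 0.1) < 1e-9))

  s2 <- make_schedule(2.0, 3.0, 0.5, 100)
  expect_equal(vapply(s2$windows, function(w) w$center, 0), c(2.0, 2.5, 3.0))

  expect_error(make_schedule(2.0, 7.0, 0.3), "integer multiple")
})

test_that("energy function matches a brute-force double-loop oracle", {
  ff <- forcefield_params(debye_length = 1.2)
  for (seed in 1:4) {
    st <- random_small_state(seed, topology = if (seed %% 2) "linear" else "ring")
    expect_equal(total_energy(st, ff), oracle_total_energy(st, ff),
                 tolerance = 1e-9)
  }
  # unscreened variant
  ff0 <- forcefield_params(debye_length = 0)
  st <- random_small_state(5)
  expect_equal(total_energy(st, ff0), oracle_total_energy(st, ff0),
               tolerance = 1e-9)
})

test_that("closed-form energy cases evaluate exactly", {
  ff <- forcefield_params()
  # two neutral beads beyond the WCA cutoff, no bonds -> zero energy
  st <- make_state(single_bead(c(5, 5, 5)), single_bead(c(6, 5, 5)),
                   edge = 50)
  expect_equal(total_energy(st, ff), 0)
  # WCA pair exactly at 2^(1/6) sigma -> cut and shifted to zero
  d <- 2^(1 / 6) * ff$wca_sigma
  st2 <- make_state(single_bead(c(5, 5, 5)), single_bead(c(5 + d, 5, 5)),
                    edge = 50)
  expect_equal(total_energy(st2, ff), 0, tolerance = 1e-12)
  # two unit charges at r = l_B interact with ~1 kT (tiny cutoff shift)
  stq <- make_state(single_bead(c(2, 2, 2)), single_bead(c(9000, 9000, 9000)),
                    ion_positions = matrix(c(5, 5, 5, 5.7, 5, 5), 2, 3,
                                           byrow = TRUE),
                    ion_charges = c(1, 1), edge = 1e4)
  expect_equal(total_energy(stq, ff) / kT(300), 1.0, tolerance = 1e-3)
  expect_equal(kT(300), 2.494, tolerance = 1e-3)
  # overlapping charges trip the numeric guard
  stov <- make_state(single_bead(c(5, 5, 5), -1), single_bead(c(5, 5, 5), -1),
                     edge = 50)
  expect_error(total_energy(stov, ff), "overlap")
})

test_that("the sampler is deterministic and exact in simple limits", {
  cfg <- preset_config("two-bead-oracle")
  ff <- forcefield_params(debye_length = 1.0)
  w <- umbrella_window(1.5, 300)
  st <- build_system(cfg, 1.5, seed = 2)

  r1 <- run_window(st, ff, w, 100, 400, 10, seed = 9)
  r2 <- run_window(st, ff, w, 100, 400, 10, seed = 9)
  expect_identical(r1$rc_series, r2$rc_series)    # bitwise reproducibility
  expect_length(r1$rc_series, 40)                  # n_prod / stride

  # flat potential, single free particle: every move accepted
  free <- make_state(single_bead(c(5, 5, 5)), single_bead(c(9, 5, 5)),
                     edge = 20)
  set.seed(1)
  res <- dnapairpmf:::run_mc_raw(free, forcefield_params(), NULL, 50, 1, 0,
                                 dnapairpmf:::default_amps(), FALSE)
  expect_equal(unname(res$acceptance[c("bead", "translate")]), c(1, 1))

  # zero-temperature limit: energy non-increasing along the chain
  chain <- build_linear_duplex_model(6, 0.4)
  chain$positions <- chain$positions + matrix(rnorm(18, 0, 0.05), 6, 3)
  chain$charges <- rep(0, 6)
  other <- single_bead(c(8, 8, 8))
  st0 <- make_state(chain, other, edge = 20)
  ff0 <- forcefield_params(temperature = 0)
  e_prev <- oracle_total_energy(st0, ff0)
  s <- st0
  for (k in 1:10) {
    s <- mc_sweep(s, ff0, rng_seed = k)
    e_now <- oracle_total_energy(s, ff0)
    expect_lte(e_now, e_prev + 1e-9)
    e_prev <- e_now
  }
})

test_that("a stiff harmonic bias yields the Gaussian rc distribution kT/k", {
  # two beads restrained at a large separation: the r^2 radial measure is
  # negligible there and the rc distribution must be N(center, kT/k)
  cfg <- preset_config("two-bead-oracle")
  cfg$system$box_edge_nm <- 80
  ff <- forcefield_params(debye_length = 1.0)
  w <- umbrella_window(30, 500)
  st <- build_system(cfg, 30, seed = 1)
  rec <- run_window(st, ff, w, n_equil_sweeps = 2000, n_prod_sweeps = 2e5,
                    sample_stride = 20, seed = 3)
  expect_length(rec$rc_series, 1e4)
  ks <- suppressWarnings(
    stats::ks.test(rec$rc_series, "pnorm", mean = 30,
                   sd = sqrt(kT(300) / 500)))
  expect_gt(ks$p.value, 0.01)
  # stiff-bias limit: sample mean at the window centre within MC error
  expect_equal(mean(rec$rc_series), 30, tolerance = 1e-3)
})

test_that("empirical state-to-state flows balance in equilibrium (3-state check)", {
  run <- get_two_bead_run()
  rec <- run$records[[8]]
  x <- rec$rc_series
  qs <- stats::quantile(x, c(1 / 3, 2 / 3))
  s <- findInterval(x, qs) + 1L
  trans <- table(factor(s[-length(s)], 1:3), factor(s[-1], 1:3))
  for (i in 1:2) for (j in (i + 1):3) {
    nij <- trans[i, j]; nji <- trans[j, i]
    if (nij + nji > 0)
      expect_lt(abs(nij - nji), 3 * sqrt(nij + nji) + 1)
  }
})
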