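# Gyration analysis, orientation angles, KDE, superposition, RMSF, g(r)
# and coordination numbers.

rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

test_that("gyration tensor closed forms and rotational invariance", {
  expect_equal(gyration_tensor(matrix(c(1, 2, 3), 1, 3)),
               matrix(0, 3, 3), ignore_attr = TRUE)
  # two points at +/- d/2 on x: one principal moment d^2/4
  d <- 1.6
  two <- rbind(c(-d / 2, 0, 0), c(d / 2, 0, 0))
  spec <- principal_axes(gyration_tensor(two))
  expect_equal(spec$eigenvalues, c(d^2 / 4, 0, 0))
  # ideal 65-bead minicircle: r_g = 3.50 nm
  ring <- build_minicircle_model(65, 0.338)
  expect_equal(round(radius_of_gyration(ring$positions), 2), 3.50)

  # eigenvalues invariant under a global rotation
  set.seed(21)
  pts <- matrix(rnorm(60), 20, 3)
  R <- rotation_matrix(c(1, 2, 3), 0.9)
  ev1 <- principal_axes(gyration_tensor(pts))$eigenvalues
  ev2 <- principal_axes(gyration_tensor(pts %*% t(R)))$eigenvalues
  expect_equal(ev1, ev2, tolerance = 1e-9)
})

test_that("principal axes are sorted, deterministic in sign, and rotate correctly", {
  spec <- principal_axes(diag(c(9, 4, 1)))
  expect_equal(spec$eigenvalues, c(9, 4, 1))
  expect_equal(abs(spec$eigenvectors), diag(3), tolerance = 1e-12)
  # sign convention: first non-zero component positive
  expect_true(all(apply(spec$eigenvectors, 2, function(v) {
    v[which(abs(v) > 1e-12)[1]] > 0
  })))
  expect_equal(spec$r_g, sqrt(14))

  R <- rotation_matrix(c(0, 1, 1), 0.6)
  spec2 <- principal_axes(R %*% diag(c(9, 4, 1)) %*% t(R))
  expect_equal(spec2$eigenvalues, c(9, 4, 1), tolerance = 1e-9)
  # rotated axes span the same directions
  for (k in 1:3) {
    v <- R[, k]
    expect_equal(abs(sum(spec2$eigenvectors[, k] * v)), 1, tolerance = 1e-9)
  }

  expect_error(principal_axes(matrix(c(1, 2, 0, 1, 1, 0, 0, 0, 1), 3, 3)),
               "symmetric")
  # identity: degenerate but stable
  expect_equal(principal_axes(diag(3))$eigenvalues, c(1, 1, 1))
})

test_that("orientation angle folds to [0, 90], is symmetric and rotation invariant", {
  rod <- function(dir, n = 10) {
    dir <- dir / sqrt(sum(dir^2))
    outer(seq(0, 3, length.out = n), dir)
  }
  expect_equal(orientation_angle(rod(c(1, 0, 0)), rod(c(1, 0, 0))),
               0, ignore_attr = TRUE)
  expect_equal(orientation_angle(rod(c(1, 0, 0)), rod(c(0, 1, 0))),
               90, ignore_attr = TRUE)
  # antiparallel folds to zero
  expect_equal(orientation_angle(rod(c(1, 0, 0)), rod(c(-1, 0, 0))),
               0, ignore_attr = TRUE, tolerance = 1e-9)
  # symmetric in arguments
  a <- rod(c(1, 0.2, 0)); b <- rod(c(0.3, 1, 0.1))
  expect_equal(orientation_angle(a, b), orientation_angle(b, a),
               tolerance = 1e-12, ignore_attr = TRUE)
  # invariant under a global rotation of the pair
  R <- rotation_matrix(c(2, -1, 0.5), 1.1)
  expect_equal(orientation_angle(a %*% t(R), b %*% t(R)),
               orientation_angle(a, b), tolerance = 1e-9,
               ignore_attr = TRUE)
  # degenerate spectrum flagged: a perfect rod has lambda2 = lambda3 = 0,
  # so the smallest-eigenvalue axis is ill-defined
  expect_warning(orientation_angle(a, b, mode = "smallest"), "degenerate")
})

test_that("ring normals: coplanar-stacked rings at 0 degrees; a tilt of alpha is recovered", {
  ring <- build_minicircle_model(40, 0.5)$positions
  ring2 <- sweep(ring, 2, c(0, 0, 2), `+`)
  expect_equal(orientation_angle(ring, ring2, mode = "smallest"), 0,
               tolerance = 1e-9, ignore_attr = TRUE)
  for (alpha in c(5, 33.3, 60, 90)) {
    Rt <- rotation_matrix(c(1, 0, 0), alpha * pi / 180)
    tilted <- ring2 %*% t(Rt)
    expect_equal(orientation_angle(ring, tilted, mode = "smallest"),
                 alpha, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("KDE normalises, matches direct evaluation and resolves clusters", {
  set.seed(8)
  r <- c(rnorm(300, 3, 0.2), rnorm(300, 5.5, 0.2))
  th <- c(rnorm(300, 20, 4), rnorm(300, 70, 4))
  k <- kde2d_field(r, th)
  expect_equal(trapz2d_test(k$grid_r, k$grid_theta, k$density), 1,
               tolerance = 1e-3)
  # direct kernel-sum evaluation at 100 random grid nodes
  ii <- sample(length(k$grid_r), 100, replace = TRUE)
  jj <- sample(length(k$grid_theta), 100, replace = TRUE)
  raw <- oracle_kde_at(r, th, k$bandwidth, k$grid_r[ii], k$grid_theta[jj])
  # the field is the raw kernel sum divided by its own grid integral
  z <- trapz2d_test(k$grid_r, k$grid_theta,
                    outer(k$grid_r, k$grid_theta,
                          function(a, b) oracle_kde_at(r, th, k$bandwidth, a, b)))
  expect_equal(k$density[cbind(ii, jj)], raw / z, tolerance = 1e-12)
  # two well-separated clusters -> two local maxima along r
  marg <- rowSums(k$density)
  local_max <- which(diff(sign(diff(marg))) == -2) + 1
  expect_gte(length(local_max), 2)

  # single cluster: argmax within one cell of the sample centroid
  k1 <- kde2d_field(rnorm(500, 4, 0.15), rnorm(500, 45, 3))
  am <- which(k1$density == max(k1$density), arr.ind = TRUE)[1, ]
  expect_lt(abs(k1$grid_r[am[1]] - 4), 2 * diff(k1$grid_r[1:2]) + 0.15 / sqrt(5))
  expect_lt(abs(k1$grid_theta[am[2]] - 45), 2 * diff(k1$grid_theta[1:2]) + 3 / sqrt(5))

  expect_error(kde2d_field(rep(2, 10), rnorm(10, 45, 1)), "bandwidth")
})

test_that("Kabsch superposition is exact on superposable sets and matches the quaternion oracle", {
  set.seed(5)
  ref <- matrix(rnorm(30), 10, 3)
  out <- kabsch_align(ref, ref)
  expect_equal(out$rmsd, 0, tolerance = 1e-12)

  R <- rotation_matrix(c(0.3, 1, -2), 1.3)
  moved <- ref %*% t(R) + matrix(c(1, -2, 0.5), 10, 3, byrow = TRUE)
  out2 <- kabsch_align(moved, ref)
  expect_lt(out2$rmsd, 1e-9)
  expect_equal(out2$aligned, ref, tolerance = 1e-9)

  # perturbed copies: rmsd equals the closed-form quaternion solution
  for (seed in 1:5) {
    set.seed(seed)
    base <- matrix(rnorm(12), 4, 3)
    pert <- base %*% t(rotation_matrix(rnorm(3), runif(1, 0, pi))) +
      matrix(rnorm(12, 0, 0.2), 4, 3)
    expect_equal(kabsch_align(pert, base)$rmsd,
                 oracle_quaternion_rmsd(pert, base), tolerance = 1e-9)
  }
  # reflections are never returned as "rotations"
  mirror <- ref; mirror[, 1] <- -mirror[, 1]
  expect_equal(det(kabsch_align(mirror, ref)$rotation), 1, tolerance = 1e-9)

  expect_error(kabsch_align(ref[1:4, ], ref), "identical dimensions")
})

test_that("RMSF vanishes for rigid motion and recovers sigma*sqrt(3) for isotropic jitter", {
  ref <- build_linear_duplex_model(12, 0.5)$positions
  frames_same <- replicate(5, ref, simplify = FALSE)
  expect_true(all(rmsf_profile(frames_same, ref)$rmsf == 0))

  # pure rigid-body motion is removed by the alignment
  frames_rigid <- lapply(1:6, function(k) {
    R <- rotation_matrix(c(k, 1, 0), 0.2 * k)
    ref %*% t(R) + matrix(c(k, -k, 2), nrow(ref), 3, byrow = TRUE)
  })
  expect_lt(max(rmsf_profile(frames_rigid, ref)$rmsf), 1e-9)

  # isotropic Gaussian jitter on an anchored set: rmsf -> sigma * sqrt(3)
  set.seed(99)
  big <- matrix(rnorm(150, sd = 3), 50, 3)
  sigma <- 0.05
  frames_j <- lapply(1:4000, function(k) big + matrix(rnorm(150, 0, sigma), 50, 3))
  rms <- rmsf_profile(frames_j, big)$rmsf
  expect_equal(mean(rms), sigma * sqrt(3), tolerance = 0.05)
})

test_that("g(r) closed forms: single pair, exclusion zone, ideal gas", {
  box <- simulation_box(10)
  # two fixed particles at distance d: one non-zero bin containing d
  f <- rbind(c(1, 1, 1), c(1, 1, 2.23))
  curve <- rdf(list(f), 1, 2, bin_width = 0.1, r_max = 4, box = box)
  nz <- which(curve$g > 0)
  expect_length(nz, 1)
  expect_true(curve$r[nz] - 0.05 <= 1.23 && 1.23 < curve$r[nz] + 0.05)

  # ideal gas: g = 1 within statistical bounds
  set.seed(31)
  n_b <- 400
  frames <- lapply(1:40, function(k) {
    rbind(c(5, 5, 5), matrix(runif(3 * n_b, 0, 10), n_b, 3))
  })
  ig <- rdf(frames, 1, 1 + seq_len(n_b), bin_width = 0.25, r_max = 5,
            box = box)
  expected_counts <- 40 * (n_b / 1000) * 4 * pi * ig$r^2 * 0.25
  z <- (ig$g - 1) * sqrt(expected_counts)
  expect_lt(max(abs(z)), 4)

  # hard exclusion: no counts below the exclusion radius
  sig <- 1.0
  frames_ex <- lapply(1:10, function(k) {
    pts <- matrix(runif(600, 0, 10), 200, 3)
    ctr <- c(5, 5, 5)
    keep <- sqrt(colSums((t(pts) - ctr)^2)) >= sig
    rbind(ctr, pts[keep, ])
  })
  gex <- rdf(frames_ex, 1, 2:150, bin_width = 0.1, r_max = 4, box = box)
  expect_true(all(gex$g[gex$r < sig - 0.05] == 0))

  expect_error(rdf(list(f), 1, 2, 0.1, r_max = 6, box = box), "half the box")
})

test_that("coordination numbers integrate g(r) correctly", {
  # g == 1: n(r_cut) = (4/3) pi r_cut^3 rho_b
  r <- seq(0.05, 3.95, by = 0.1)
  curve <- structure(data.frame(r = r, g = rep(1, length(r))),
                     class = c("rdf_curve", "data.frame"),
                     rho_b = 0.4, n_a = 1, n_b = 256, bin_width = 0.1)
  expect_equal(coordination_number(curve, 2.0), (4 / 3) * pi * 8 * 0.4,
               tolerance = 2e-3)
  # g == 0 below the cut
  curve0 <- curve; curve0$g <- 0
  expect_equal(coordination_number(curve0, 2.0), 0)
  # single narrow shell at r0 with unit area: 4 pi rho r0^2 * area
  r0 <- 1.55; width <- 0.1
  curve1 <- curve; curve1$g <- ifelse(abs(r - r0) < width / 2, 1 / width, 0)
  got <- coordination_number(curve1, 2.5)
  expect_equal(got, 4 * pi * 0.4 * r0^2, tolerance = 0.02)

  # ideal gas integrated to the minimum-image limit L/2 captures pi/6 of N_B
  box <- simulation_box(10)
  set.seed(12)
  n_b <- 500
  frames <- lapply(1:30, function(k)
    rbind(c(5, 5, 5), matrix(runif(3 * n_b, 0, 10), n_b, 3)))
  ig <- rdf(frames, 1, 1 + seq_len(n_b), bin_width = 0.25, r_max = 5,
            box = box)
  expect_equal(coordination_number(ig, 5) / n_b, pi / 6, tolerance = 0.03)

  # first-shell locator: minimum after the first peak
  rs <- seq(0.05, 2.95, 0.1)
  gsyn <- 1 + 2.5 * exp(-((rs - 0.8) / 0.15)^2) - 0.6 * exp(-((rs - 1.3) / 0.2)^2)
  cs <- structure(data.frame(r = rs, g = gsyn),
                  class = c("rdf_curve", "data.frame"),
                  rho_b = 0.1, n_a = 1, n_b = 100, bin_width = 0.1)
  expect_equal(first_shell_radius(cs, smooth = 0), 1.35, tolerance = 0.11)
})
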