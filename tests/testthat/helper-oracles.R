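# Independent oracles and shared fixtures. Everything here is deliberately
# naive (double loops, closed forms) so it cannot share a defect with the
# implementation it checks.

# ---- brute-force energy oracle -------------------------------------------
# Double-loop re-derivation of the coarse-grained Hamiltonian from its
# definition: harmonic bonds/angles from the construction geometry, WCA on
# non-bonded pairs, screened Coulomb (cut & shifted at edge/2) on charged
# pairs, minimum image.
oracle_total_energy <- function(state, ff) {
  pos <- system_positions(state)
  q <- system_charges(state)
  edge <- state$box$edge
  n <- nrow(pos)
  mi <- function(d) d - edge * round(d / edge)
  kbt <- ff$kT
  rcut <- edge / 2
  kern <- function(r) if (ff$debye_length > 0) exp(-r / ff$debye_length) / r else 1 / r
  rmin <- 2^(1 / 6) * ff$wca_sigma

  # bonded pairs (1-2) per molecule; equilibrium values are model
  # parameters (frozen at construction), re-used here as inputs
  bonded <- list()
  e <- 0
  off <- 0
  for (mol in list(state$molecule_a, state$molecule_b)) {
    nb <- mol$n_bp
    pairs <- if (nb >= 2) cbind(seq_len(nb - 1), 2:nb) else NULL
    if (mol$topology == "ring") pairs <- rbind(pairs, c(nb, 1))
    if (!is.null(pairs)) {
      for (k in seq_len(nrow(pairs))) {
        i <- pairs[k, 1]; j <- pairs[k, 2]
        r <- sqrt(sum((pos[off + i, ] - pos[off + j, ])^2))
        e <- e + 0.5 * ff$bond_k * (r - mol$bond_r0[k])^2
        bonded[[length(bonded) + 1]] <- c(off + i, off + j)
      }
    }
    n_ang <- if (mol$topology == "ring") nb else nb - 2
    if (nb >= 3 && n_ang > 0) {
      for (k in seq_len(n_ang)) {
        idx <- function(m) ((m - 1) %% nb) + 1
        i <- idx(k); j <- idx(k + 1); l <- idx(k + 2)
        pm <- pos[off + c(i, j, l), , drop = FALSE]
        u <- pm[1, ] - pm[2, ]; v <- pm[3, ] - pm[2, ]
        th <- acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
        e <- e + 0.5 * ff$bend_k * (th - mol$angle_theta0[k])^2
      }
    }
    off <- off + nb
  }
  is_bonded <- function(i, j) {
    any(vapply(bonded, function(b) all(sort(b) == sort(c(i, j))), TRUE))
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum(mi(pos[i, ] - pos[j, ])^2))
      if (!is_bonded(i, j) && d < rmin) {
        sr6 <- (ff$wca_sigma / d)^6
        e <- e + 4 * ff$wca_epsilon * (sr6^2 - sr6) + ff$wca_epsilon
      }
      if (q[i] * q[j] != 0 && d < rcut)
        e <- e + kbt * ff$bjerrum_length * q[i] * q[j] * (kern(d) - kern(rcut))
    }
  }
  e
}

# ---- quaternion superposition oracle -------------------------------------
# Horn's closed-form quaternion method: the optimal rotation is the
# eigenvector of the 4x4 key matrix with the largest eigenvalue. Entirely
# independent of the SVD-based Kabsch implementation.
oracle_quaternion_rmsd <- function(mobile, reference) {
  x <- sweep(mobile, 2, colMeans(mobile))
  y <- sweep(reference, 2, colMeans(reference))
  M <- crossprod(x, y)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(x^2) + sum(y^2) - 2 * lam) / nrow(x)
  sqrt(max(msd, 0))
}

# ---- naive KDE evaluation -------------------------------------------------
oracle_kde_at <- function(r, theta, h, at_r, at_theta) {
  n <- length(r)
  mapply(function(gr, gt) {
    sum(dnorm((gr - r) / h[1]) * dnorm((gt - theta) / h[2])) /
      (n * h[1] * h[2])
  }, at_r, at_theta)
}

# ---- independent 2D trapezoid (via pracma) --------------------------------
trapz2d_test <- function(gx, gy, f) {
  pracma::trapz(gx, apply(f, 1, function(row) pracma::trapz(gy, row)))
}

# ---- exact Gaussian umbrella sampling of a 1D harmonic potential ----------
# For U(x) = 0.5 * a * (x - x0)^2 under bias 0.5 * k * (x - c)^2 the biased
# distribution is Gaussian with the moments below; sampling it exactly
# removes all sampler error from WHAM checks.
harmonic_toy_records <- function(a, x0, k, centers, n_per_window, seed,
                                 temperature = 300) {
  kbt <- kT(temperature)
  set.seed(seed)
  lapply(centers, function(c0) {
    mu <- (a * x0 + k * c0) / (a + k)
    s <- sqrt(kbt / (a + k))
    window_record(umbrella_window(c0, k), rnorm(n_per_window, mu, s))
  })
}

# ---- manually assembled system states -------------------------------------
# Build a system_state without the placement machinery (for closed-form
# energy cases and random small systems).
make_state <- function(mol_a, mol_b, ion_positions = matrix(0, 0, 3),
                       ion_charges = numeric(0), edge = 50) {
  structure(list(molecule_a = mol_a, molecule_b = mol_b,
                 ion_positions = ion_positions, ion_charges = ion_charges,
                 box = simulation_box(edge)),
            class = "system_state")
}

single_bead <- function(xyz, charge = 0) {
  molecule_model(matrix(xyz, 1, 3), charge, "linear")
}

random_small_state <- function(seed, topology = "linear") {
  set.seed(seed)
  n_bp <- sample(3:8, 1)
  mol <- function() {
    m <- if (topology == "ring") build_minicircle_model(n_bp, 0.4)
         else build_linear_duplex_model(n_bp, 0.4)
    m$positions <- m$positions + matrix(runif(3, 4, 8), n_bp, 3, byrow = TRUE)
    # small perturbation so bonded terms are non-trivial
    m$positions <- m$positions + matrix(rnorm(3 * n_bp, 0, 0.03), n_bp, 3)
    m
  }
  n_ion <- sample(5:15, 1)
  make_state(mol(), mol(),
             ion_positions = matrix(runif(3 * n_ion, 0, 12), n_ion, 3),
             ion_charges = sample(c(-1, 1, 2), n_ion, replace = TRUE),
             edge = 12)
}

# ---- shared Debye-Hueckel two-bead umbrella run ---------------------------
# The end-to-end fixture used by several WHAM/consistency tests; computed
# once per session and cached.
.fixture_env <- new.env(parent = emptyenv())

get_two_bead_run <- function() {
  if (!is.null(.fixture_env$two_bead)) return(.fixture_env$two_bead)
  cfg <- preset_config("two-bead-oracle")
  ff <- forcefield_params(debye_length = cfg$forcefield$debye_length)
  sched <- make_schedule(cfg$sampling$r_min, cfg$sampling$r_max,
                         cfg$sampling$spacing, cfg$sampling$force_k)
  records <- lapply(seq_along(sched$windows), function(i) {
    w <- sched$windows[[i]]
    st <- build_system(cfg, w$center, seed = 100 + i)
    run_window(st, ff, w, n_equil_sweeps = cfg$sampling$n_equil_sweeps,
               n_prod_sweeps = cfg$sampling$n_prod_sweeps,
               sample_stride = cfg$sampling$sample_stride, seed = 100 + i)
  })
  .fixture_env$two_bead <- list(cfg = cfg, ff = ff, records = records,
                                edges = seq(cfg$wham$bin_min,
                                            cfg$wham$bin_max,
                                            by = cfg$wham$bin_width))
  .fixture_env$two_bead
}
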