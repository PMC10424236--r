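# Coarse-grained Hamiltonian and Metropolis sampler. The model is an
# implicit-solvent bead model: harmonic bonds and angle bending along each
# backbone, WCA repulsion between non-bonded sites, and a (optionally
# Debye-screened) Coulomb term kT * l_B * z_i z_j * exp(-r/lambda_D) / r
# between all charged pairs, spherically cut and shifted at half the box
# edge. Counterion condensation and release arise from the explicit ions;
# by default no background screening is applied (debye_length = 0 means the
# bare 1/r kernel with l_B = 0.7 nm, i.e. water at 300 K).

#' Coarse-grained force-field parameters
#'
#' @param bond_k Harmonic bond constant, kJ/mol/nm^2. The default is stiff
#'   enough to keep the construction geometry at 300 K.
#' @param bend_k Harmonic angle constant, kJ/mol/rad^2. The default
#'   `kT * l_p / rise` with persistence length l_p = 50 nm gives DNA-like
#'   stiffness for a 0.338 nm bead spacing.
#' @param wca_sigma WCA diameter in nm, applied to every non-bonded site
#'   pair.
#' @param wca_epsilon WCA energy scale in kJ/mol.
#' @param bjerrum_length Bjerrum length in nm (0.7 for water at 300 K).
#' @param debye_length Debye screening length in nm; 0 means unscreened
#'   (bare Coulomb between the explicit charges).
#' @param temperature Temperature in K; `kT` is derived as `R * T`.
#' @return An object of class `forcefield_params`.
#' @export
forcefield_params <- function(bond_k = 8000,
                              bend_k = kT(300) * 50 / phys_const$BDNA_RISE_NM,
                              wca_sigma = 0.35,
                              wca_epsilon = kT(300),
                              bjerrum_length = phys_const$BJERRUM_WATER_300K,
                              debye_length = 0,
                              temperature = 300) {
  vals <- c(bond_k = bond_k, bend_k = bend_k, wca_sigma = wca_sigma,
            wca_epsilon = wca_epsilon, bjerrum_length = bjerrum_length)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all force-field parameters must be positive")
  if (debye_length < 0) stop("debye_length must be >= 0")
  if (temperature < 0) stop("temperature must be >= 0")
  structure(list(bond_k = bond_k, bend_k = bend_k, wca_sigma = wca_sigma,
                 wca_epsilon = wca_epsilon, bjerrum_length = bjerrum_length,
                 debye_length = debye_length, temperature = temperature,
                 kT = phys_const$R_GAS * temperature),
            class = "forcefield_params")
}

#' Harmonic umbrella window
#'
#' @param center Window centre on the COM-separation coordinate, nm (> 0).
#' @param force_k Harmonic force constant, kJ/mol/nm^2 (default 5000, the
#'   value used for the DNA pair systems).
#' @return An object of class `umbrella_window`.
#' @export
umbrella_window <- function(center, force_k = 5000) {
  if (!is.numeric(center) || center <= 0) stop("window center must be > 0")
  if (!is.numeric(force_k) || force_k <= 0) stop("force_k must be > 0")
  structure(list(center = as.numeric(center), force_k = as.numeric(force_k)),
            class = "umbrella_window")
}

#' Umbrella-window schedule with uniform spacing
#'
#' The default reproduces the production protocol: windows every 0.1 nm from
#' 2 to 7 nm (51 windows) with force constant 5000 kJ/mol/nm^2.
#'
#' @param r_min,r_max First and last window centre, nm.
#' @param spacing Uniform window spacing, nm; `(r_max - r_min)` must be an
#'   integer multiple of it (within 1e-9).
#' @param force_k Force constant shared by all windows, kJ/mol/nm^2.
#' @return An object of class `window_schedule`: a list with `windows` (list
#'   of [umbrella_window()]) and `spacing`.
#' @examples
#' length(make_schedule(2, 7, 0.1, 5000)$windows)  # 51
#' @export
make_schedule <- function(r_min = 2.0, r_max = 7.0, spacing = 0.1,
                          force_k = 5000) {
  if (r_min >= r_max) stop("r_min must be smaller than r_max")
  if (spacing <= 0) stop("spacing must be positive")
  k <- (r_max - r_min) / spacing
  if (abs(k - round(k)) > 1e-9)
    stop("(r_max - r_min) must be an integer multiple of spacing")
  centers <- r_min + spacing * seq(0, round(k))
  structure(list(windows = lapply(centers, umbrella_window, force_k = force_k),
                 spacing = spacing),
            class = "window_schedule")
}

#' Centre-of-mass separation of the DNA pair
#'
#' Euclidean distance between the two molecules' unweighted bead centroids,
#' computed on unwrapped molecular coordinates. No minimum image is applied
#' across the reaction coordinate; this is valid because the largest sampled
#' separation (7 nm) is below half the box edge.
#'
#' @param state A `system_state`.
#' @return Separation in nm.
#' @export
com_separation <- function(state) {
  stopifnot(inherits(state, "system_state"))
  d <- colMeans(state$molecule_a$positions) -
       colMeans(state$molecule_b$positions)
  sqrt(sum(d * d))
}

#' Umbrella bias energy
#'
#' `0.5 * force_k * (r - center)^2`; with the production force constant
#' 5000 kJ/mol/nm^2 a 0.1 nm excursion costs 25 kJ/mol.
#'
#' @param w An [umbrella_window()].
#' @param r Reaction-coordinate value(s), nm.
#' @return Bias energy in kJ/mol (vectorised over `r`).
#' @export
bias_energy <- function(w, r) {
  stopifnot(inherits(w, "umbrella_window"), all(r > 0))
  0.5 * w$force_k * (r - w$center)^2
}

# Bonded topology (bonds + angles) of one molecule, 0-based indices offset
# by `offset`. Equilibrium lengths/angles are the ones frozen on the model
# at construction.
bonded_topology <- function(mol, offset = 0L) {
  n <- mol$n_bp
  bi <- bj <- integer(0)
  ai <- aj <- ak <- integer(0)
  if (n >= 2) {
    pairs <- cbind(seq_len(n - 1), seq_len(n - 1) + 1L)
    if (mol$topology == "ring") pairs <- rbind(pairs, c(n, 1L))
    bi <- pairs[, 1]; bj <- pairs[, 2]
  }
  n_ang <- if (mol$topology == "ring") n else n - 2L
  if (n >= 3 && n_ang > 0) {
    idx <- function(k) ((k - 1L) %% n) + 1L
    first <- seq_len(n_ang)
    ai <- idx(first); aj <- idx(first + 1L); ak <- idx(first + 2L)
  }
  list(bi = as.integer(bi - 1L + offset), bj = as.integer(bj - 1L + offset),
       br0 = mol$bond_r0,
       ai = as.integer(ai - 1L + offset), aj = as.integer(aj - 1L + offset),
       ak = as.integer(ak - 1L + offset), ath0 = mol$angle_theta0)
}

system_topology <- function(state) {
  ta <- bonded_topology(state$molecule_a, 0L)
  tb <- bonded_topology(state$molecule_b, state$molecule_a$n_bp)
  list(bi = c(ta$bi, tb$bi), bj = c(ta$bj, tb$bj), br0 = c(ta$br0, tb$br0),
       ai = c(ta$ai, tb$ai), aj = c(ta$aj, tb$aj), ak = c(ta$ak, tb$ak),
       ath0 = c(ta$ath0, tb$ath0))
}

#' Total potential energy of a system
#'
#' Sum of harmonic bonds along each backbone (ring-closure bond included for
#' rings), harmonic angle bending on consecutive backbone triplets (cyclic
#' for rings), WCA repulsion between all non-bonded site pairs, and the
#' screened Coulomb term between all charged pairs (minimum image, cut and
#' shifted at half the box edge). Overlapping point charges (r < 1e-6 nm)
#' raise an error.
#'
#' @param state A `system_state`.
#' @param ff A [forcefield_params()].
#' @return Energy in kJ/mol.
#' @export
total_energy <- function(state, ff) {
  stopifnot(inherits(state, "system_state"), inherits(ff, "forcefield_params"))
  top <- system_topology(state)
  cpp_total_energy(system_positions(state), system_charges(state),
                   top$bi, top$bj, top$br0, top$ai, top$aj, top$ak, top$ath0,
                   unclass(ff), state$box$edge)
}

default_amps <- function() c(ion = 0.3, bead = 0.05, translate = 0.05,
                             rotate = 0.1)

run_mc_raw <- function(state, ff, w, n_sweeps, sample_stride, frame_stride,
                       amps, tune) {
  top <- system_topology(state)
  cpp_run_mc(system_positions(state), system_charges(state),
             state$molecule_a$n_bp, state$molecule_b$n_bp,
             top$bi, top$bj, top$br0, top$ai, top$aj, top$ak, top$ath0,
             unclass(ff), state$box$edge,
             if (is.null(w)) 1 else w$center, if (is.null(w)) 0 else w$force_k,
             as.integer(n_sweeps), as.integer(sample_stride),
             as.integer(frame_stride), as.numeric(amps), isTRUE(tune))
}

state_with_positions <- function(state, pos) {
  nA <- state$molecule_a$n_bp; nB <- state$molecule_b$n_bp
  state$molecule_a$positions <- pos[seq_len(nA), , drop = FALSE]
  state$molecule_b$positions <- pos[nA + seq_len(nB), , drop = FALSE]
  if (nrow(pos) > nA + nB)
    state$ion_positions <- pos[(nA + nB + 1):nrow(pos), , drop = FALSE]
  state
}

#' One Metropolis Monte Carlo sweep
#'
#' A sweep is one trial displacement per ion plus, for each molecule, one
#' trial displacement per bead, one rigid COM translation and one rigid
#' rotation about the COM; each move is accepted with probability
#' `min(1, exp(-dE/kT))` where `dE` includes the umbrella bias. The chain
#' satisfies detailed balance with respect to `exp(-(U + bias)/kT)`.
#'
#' @param state A `system_state`.
#' @param ff A [forcefield_params()].
#' @param w An [umbrella_window()], or `NULL` for unbiased sampling.
#' @param rng_seed Integer seed (fixed seed gives a bitwise-reproducible
#'   sweep).
#' @param amps Move amplitudes `c(ion, bead, translate, rotate)` in nm
#'   (radians for the rotation).
#' @return The updated `system_state`.
#' @export
mc_sweep <- function(state, ff, w = NULL, rng_seed = 1L,
                     amps = default_amps()) {
  set.seed(as.integer(rng_seed))
  res <- run_mc_raw(state, ff, w, 1L, 0L, 0L, amps, FALSE)
  state_with_positions(state, res$positions)
}

#' Run one umbrella window
#'
#' Equilibrates with move-amplitude auto-tuning (targeting 30-50%
#' acceptance), freezes the amplitudes, then runs production recording the
#' COM separation every `sample_stride` sweeps and, optionally, full
#' coordinate frames every `frame_stride` sweeps.
#'
#' @param state0 Starting `system_state`.
#' @param ff A [forcefield_params()].
#' @param w An [umbrella_window()].
#' @param n_equil_sweeps,n_prod_sweeps Equilibration / production sweep
#'   counts.
#' @param sample_stride Record the reaction coordinate every this many
#'   production sweeps; must divide `n_prod_sweeps`.
#' @param seed Integer seed; fixed seed gives identical output.
#' @param frame_stride Record a coordinate frame every this many sweeps
#'   (0 = no frames).
#' @return An object of class `window_record`: `window`, `rc_series`,
#'   `frames` (list of coordinate matrices), `seed`, `acceptance`,
#'   `final_state`, `n_dna` (beads per molecule).
#' @export
run_window <- function(state0, ff, w, n_equil_sweeps = 5e3,
                       n_prod_sweeps = 5e4, sample_stride = 10, seed = 1L,
                       frame_stride = 0L) {
  stopifnot(inherits(state0, "system_state"),
            inherits(ff, "forcefield_params"),
            inherits(w, "umbrella_window"))
  if (n_prod_sweeps %% sample_stride != 0)
    stop("sample_stride must divide n_prod_sweeps")
  set.seed(as.integer(seed))
  eq <- run_mc_raw(state0, ff, w, n_equil_sweeps, 0L, 0L,
                   default_amps(), TRUE)
  st <- state_with_positions(state0, eq$positions)
  pr <- run_mc_raw(st, ff, w, n_prod_sweeps, sample_stride, frame_stride,
                   eq$amps, FALSE)
  structure(
    list(window = w,
         rc_series = pr$rc_series,
         frames = pr$frames,
         seed = as.integer(seed),
         acceptance = pr$acceptance,
         final_state = state_with_positions(st, pr$positions),
         n_dna = c(state0$molecule_a$n_bp, state0$molecule_b$n_bp)),
    class = "window_record")
}

#' Analytic non-bonded pair energy of the coarse-grained model
#'
#' The WCA plus screened-Coulomb interaction of two isolated sites exactly
#' as the sampler evaluates it (minimum image irrelevant for r < edge/2;
#' Coulomb cut and shifted at `edge/2`). This closed form is the oracle for
#' the two-bead pipeline check: the effective potential of two isolated
#' beads equals `U(r) - U(r_ref) - 2 kT ln(r / r_ref)` — the second term is
#' the radial-measure contribution that distance-WHAM leaves in place.
#'
#' @param r Separation(s), nm.
#' @param q1,q2 Site charges, e.
#' @param ff A [forcefield_params()].
#' @param box_edge Box edge, nm (sets the Coulomb cutoff `edge/2`).
#' @return Energy in kJ/mol, vectorised over `r`.
#' @export
pair_energy_analytic <- function(r, q1, q2, ff, box_edge) {
  stopifnot(inherits(ff, "forcefield_params"), all(r > 0))
  rcut <- box_edge / 2
  kern <- function(x) {
    if (ff$debye_length > 0) exp(-x / ff$debye_length) / x else 1 / x
  }
  coul <- ifelse(r < rcut,
                 ff$kT * ff$bjerrum_length * q1 * q2 * (kern(r) - kern(rcut)),
                 0)
  rmin <- 2^(1 / 6) * ff$wca_sigma
  sr6 <- (ff$wca_sigma / r)^6
  wca <- ifelse(r < rmin, 4 * ff$wca_epsilon * (sr6^2 - sr6) + ff$wca_epsilon,
                0)
  coul + wca
}

#' Expected two-bead effective potential
#'
#' `U(r) - U(r_ref) - 2 kT ln(r / r_ref)`: the closed-form effective
#' potential that distance-WHAM (no Jacobian correction) recovers for two
#' isolated interacting beads, referenced to zero at `reference_r`.
#'
#' @inheritParams pair_energy_analytic
#' @param reference_r Reference separation, nm.
#' @return Energy in kJ/mol, vectorised over `r`.
#' @export
two_bead_expected_pmf <- function(r, q1, q2, ff, box_edge, reference_r) {
  pair_energy_analytic(r, q1, q2, ff, box_edge) -
    pair_energy_analytic(reference_r, q1, q2, ff, box_edge) -
    2 * ff$kT * log(r / reference_r)
}

#' Construct a window record from an existing reaction-coordinate series
#'
#' Useful for feeding externally generated (for example analytically
#' sampled) series into the WHAM layer.
#'
#' @param window An [umbrella_window()].
#' @param rc_series Numeric vector of positive reaction-coordinate samples.
#' @param seed Optional integer bookkeeping seed.
#' @return A `window_record`.
#' @export
window_record <- function(window, rc_series, seed = NA_integer_) {
  stopifnot(inherits(window, "umbrella_window"))
  rc_series <- as.numeric(rc_series)
  if (length(rc_series) == 0) stop("rc_series must be nonempty")
  if (any(!is.finite(rc_series)) || any(rc_series <= 0))
    stop("all rc_series values must be positive and finite")
  structure(list(window = window, rc_series = rc_series, frames = list(),
                 seed = seed, acceptance = NULL, final_state = NULL,
                 n_dna = NULL),
            class = "window_record")
}
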