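# Coarse-grained structure builders: one bead per base pair carrying the
# charge of both strands' phosphates (-2 e), so the linear charge density
# (-2 e / 0.338 nm) matches double-stranded DNA.

#' Construct a molecule model
#'
#' Low-level constructor for a coarse-grained DNA model. Most users should
#' call [build_linear_duplex_model()] or [build_minicircle_model()]; the
#' constructor is exported so that reduced test systems (for example a single
#' charged bead) can be assembled directly.
#'
#' @param positions Numeric matrix, one row per bead, columns x/y/z in nm.
#' @param charges Numeric vector of per-bead charges in elementary charge
#'   units; all non-zero entries must be negative (polyanion).
#' @param topology `"linear"` or `"ring"`.
#' @param bead_radius Bead radius in nm (bookkeeping only; sterics are set by
#'   the force field's WCA sigma).
#' @return An object of class `molecule_model`.
#' @export
molecule_model <- function(positions, charges, topology = c("linear", "ring"),
                           bead_radius = 1.0) {
  topology <- match.arg(topology)
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must have 3 columns (x, y, z in nm)")
  storage.mode(positions) <- "double"
  charges <- as.numeric(charges)
  if (length(charges) != nrow(positions))
    stop("charges must have one entry per bead")
  if (any(charges > 0))
    stop("DNA bead charges must be negative or zero")
  if (topology == "ring" && nrow(positions) < 3)
    stop("a ring needs at least 3 beads")
  n <- nrow(positions)
  # equilibrium bonded geometry, frozen at construction: harmonic bonds and
  # angles restore the model towards this reference, however the beads move
  bond_pairs <- NULL
  if (n >= 2) {
    bond_pairs <- cbind(seq_len(n - 1), seq_len(n - 1) + 1L)
    if (topology == "ring") bond_pairs <- rbind(bond_pairs, c(n, 1L))
  }
  bond_r0 <- if (is.null(bond_pairs)) numeric(0) else
    sqrt(rowSums((positions[bond_pairs[, 1], , drop = FALSE] -
                  positions[bond_pairs[, 2], , drop = FALSE])^2))
  n_ang <- if (topology == "ring") n else n - 2L
  angle_theta0 <- numeric(0)
  if (n >= 3 && n_ang > 0) {
    idx <- function(k) ((k - 1L) %% n) + 1L
    first <- seq_len(n_ang)
    u <- positions[idx(first), , drop = FALSE] -
         positions[idx(first + 1L), , drop = FALSE]
    v <- positions[idx(first + 2L), , drop = FALSE] -
         positions[idx(first + 1L), , drop = FALSE]
    cosang <- rowSums(u * v) / (sqrt(rowSums(u * u)) * sqrt(rowSums(v * v)))
    angle_theta0 <- acos(pmin(1, pmax(-1, cosang)))
  }
  structure(
    list(positions = positions, charges = charges, topology = topology,
         n_bp = n, bead_radius = bead_radius,
         bond_r0 = bond_r0, angle_theta0 = angle_theta0),
    class = "molecule_model")
}

#' @export
print.molecule_model <- function(x, ...) {
  cat(sprintf("<molecule_model> %s, %d beads, total charge %+g e\n",
              x$topology, x$n_bp, sum(x$charges)))
  invisible(x)
}

#' Build a coarse-grained linear DNA duplex
#'
#' A straight rod of `n_bp` beads spaced by the B-DNA rise along the x axis.
#' Beads 2..n carry -2 e each (the two phosphates of a base-pair step); bead 1
#' is neutral, so a duplex with free 5' ends and no 5'-terminal phosphates has
#' total charge -2(n_bp - 1) e, i.e. -46 e for 24 bp. This matches the charge
#' balance implied by the monovalent ion inventory of the reference systems
#' (295 Na+ - 203 Cl- = 92 e per pair of 24-mers).
#'
#' @param n_bp Number of base pairs (>= 2).
#' @param rise Rise per base pair in nm (default 0.338, canonical B-DNA).
#' @return A [molecule_model()] with `topology = "linear"`.
#' @examples
#' m <- build_linear_duplex_model(24)
#' sum(m$charges)  # -46
#' @export
build_linear_duplex_model <- function(n_bp, rise = phys_const$BDNA_RISE_NM) {
  if (!is.numeric(n_bp) || n_bp < 2) stop("n_bp must be at least 2")
  if (!is.numeric(rise) || rise <= 0) stop("rise must be positive")
  n_bp <- as.integer(n_bp)
  pos <- cbind(x = (seq_len(n_bp) - 1) * rise, y = 0, z = 0)
  chg <- c(0, rep(-2, n_bp - 1))
  molecule_model(pos, chg, "linear")
}

#' Build a coarse-grained DNA minicircle
#'
#' A planar regular `n_bp`-gon with circumference `n_bp * rise` (circle radius
#' `n_bp * rise / (2 pi)`), every bead carrying -2 e. The model is torsionally
#' relaxed (no twist is represented). For 65 bp at rise 0.338 nm the radius of
#' gyration of the ideal ring is 3.50 nm.
#'
#' @inheritParams build_linear_duplex_model
#' @return A [molecule_model()] with `topology = "ring"`, lying in the
#'   xy-plane and centred at the origin.
#' @examples
#' ring <- build_minicircle_model(65)
#' sqrt(sum(gyration_tensor(ring$positions) * diag(3)))  # ~3.50 nm
#' @export
build_minicircle_model <- function(n_bp, rise = phys_const$BDNA_RISE_NM) {
  if (!is.numeric(n_bp) || n_bp < 3) stop("n_bp must be at least 3 for a ring")
  if (!is.numeric(rise) || rise <= 0) stop("rise must be positive")
  n_bp <- as.integer(n_bp)
  radius <- n_bp * rise / (2 * pi)
  phi <- 2 * pi * (seq_len(n_bp) - 1) / n_bp
  pos <- cbind(x = radius * cos(phi), y = radius * sin(phi), z = 0)
  molecule_model(pos, rep(-2, n_bp), "ring")
}

#' Cubic periodic simulation box
#'
#' @param edge Box edge length in nm.
#' @param periodic Logical; minimum-image convention applies when `TRUE`.
#' @return An object of class `simulation_box`.
#' @export
simulation_box <- function(edge = 15.0, periodic = TRUE) {
  if (!is.numeric(edge) || edge <= 0) stop("box edge must be positive")
  structure(list(edge = as.numeric(edge), periodic = isTRUE(periodic)),
            class = "simulation_box")
}

#' Compose the ionic inventory for a DNA pair at a given bulk salt
#'
#' Counts the explicit cations and Cl- co-ions needed to (i) neutralise the
#' DNA pair and (ii) realise a bulk salt concentration `salt_molar` in the
#' nominal box volume `edge^3`:
#' `n_anions = round(salt_molar * V * N_A)`, rounded *up* to the nearest even
#' integer for divalent salt so that CaCl2 units are integral;
#' `n_counterions = |Q_DNA| / valence + n_anions / valence`.
#' With a 15.0 nm box and 0.1 M this yields 203 (monovalent) or 204
#' (divalent) anions, hence 295 Na+ or 148 Ca2+ for a pair of 24-bp duplexes
#' (total charge -92 e).
#'
#' If `|Q_DNA|` is not divisible by the valence the integer residue is
#' recorded in the returned object (`residue`, in e); [place_pair_and_ions()]
#' then adds one reduced-charge counterion of `+residue` e so the assembled
#' system is exactly neutral.
#'
#' @param total_dna_charge Total charge of the DNA pair in e (negative).
#' @param counterion_valence 1 (Na+) or 2 (Ca2+).
#' @param salt_molar Bulk salt concentration in mol/L.
#' @param box A [simulation_box()].
#' @return An object of class `ion_inventory` with fields
#'   `counterion_valence`, `n_counterions`, `n_coions`, `coion_valence` (-1)
#'   and `residue`.
#' @examples
#' compose_ion_inventory(-92, 1, 0.1, simulation_box(15))  # 295 Na+, 203 Cl-
#' compose_ion_inventory(-92, 2, 0.1, simulation_box(15))  # 148 Ca2+, 204 Cl-
#' @export
compose_ion_inventory <- function(total_dna_charge, counterion_valence,
                                  salt_molar, box) {
  if (!is.numeric(total_dna_charge) || total_dna_charge >= 0)
    stop("total_dna_charge must be negative")
  if (!counterion_valence %in% c(1L, 2L))
    stop("counterion_valence must be 1 or 2")
  if (!is.numeric(salt_molar) || salt_molar < 0)
    stop("salt_molar must be non-negative")
  stopifnot(inherits(box, "simulation_box"))
  v <- as.integer(counterion_valence)
  # box volume in litres: 1 nm^3 = 1e-24 L
  vol_litre <- box$edge^3 * 1e-24
  n_anion_exact <- salt_molar * vol_litre * phys_const$N_A
  n_anions <- if (v == 2L) {
    2L * as.integer(ceiling(n_anion_exact / 2))  # up to nearest even
  } else {
    as.integer(round(n_anion_exact))
  }
  q <- abs(total_dna_charge)
  residue <- as.integer(round(q)) %% v
  n_neut <- (as.integer(round(q)) - residue) %/% v
  if (n_anions %% v != 0L)
    stop("salt anion count not divisible by the counterion valence")
  structure(
    list(counterion_valence = v,
         n_counterions = n_neut + n_anions %/% v,
         n_coions = n_anions,
         coion_valence = -1L,
         residue = residue),
    class = "ion_inventory")
}

#' @export
print.ion_inventory <- function(x, ...) {
  cat(sprintf("<ion_inventory> %d cations (+%d e), %d Cl-%s\n",
              x$n_counterions, x$counterion_valence, x$n_coions,
              if (x$residue > 0)
                sprintf(" (+1 adjustment ion of +%d e)", x$residue) else ""))
  invisible(x)
}

#' Place a parallel-oriented DNA pair and its ions in a periodic box
#'
#' The two molecules are placed parallel-oriented, centred in the box with
#' their centres of mass separated by `com_separation` along the z axis:
#' linear rods with parallel axes (along x), rings coplanar-stacked with
#' parallel planes (xy). Ions are placed by rejection sampling, uniform in the
#' box, honouring two exclusion distances: at least 0.5 nm from any DNA bead
#' and at least 0.35 nm from any previously placed ion (minimum image).
#'
#' @param a,b [molecule_model()] objects (the pair).
#' @param inventory An [ion_inventory()].
#' @param box A [simulation_box()].
#' @param com_separation Centre-of-mass separation in nm
#'   (must be `< box$edge / 2`).
#' @param seed Integer seed; placement is deterministic under a fixed seed.
#' @param max_attempts Rejection-sampling attempts allowed per ion before
#'   giving up with a packing diagnostic.
#' @return An object of class `system_state` with fields `molecule_a`,
#'   `molecule_b`, `ion_positions`, `ion_charges`, `box`.
#' @export
place_pair_and_ions <- function(a, b, inventory, box, com_separation,
                                seed = 1L, max_attempts = 20000L) {
  stopifnot(inherits(a, "molecule_model"), inherits(b, "molecule_model"),
            inherits(inventory, "ion_inventory"),
            inherits(box, "simulation_box"))
  if (com_separation >= box$edge / 2)
    stop("com_separation must be smaller than half the box edge")
  half <- box$edge / 2
  centre <- c(half, half, half)

  recentre <- function(m, dz) {
    com <- colMeans(m$positions)
    m$positions <- sweep(m$positions, 2, com) +
      matrix(centre + c(0, 0, dz), nrow(m$positions), 3, byrow = TRUE)
    m
  }
  a <- recentre(a, -com_separation / 2)
  b <- recentre(b, +com_separation / 2)

  dna <- rbind(a$positions, b$positions)
  n_ions <- inventory$n_counterions + inventory$n_coions +
    (inventory$residue > 0)
  ion_q <- c(rep(inventory$counterion_valence, inventory$n_counterions),
             if (inventory$residue > 0) inventory$residue,
             rep(inventory$coion_valence, inventory$n_coions))

  set.seed(as.integer(seed))
  pos <- matrix(NA_real_, n_ions, 3)
  edge <- box$edge
  min_img2 <- function(d) {
    d <- d - edge * round(d / edge)
    rowSums(d * d)
  }
  for (i in seq_len(n_ions)) {
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      p <- stats::runif(3, 0, edge)
      if (min(min_img2(sweep(dna, 2, p))) < 0.5^2) next
      if (i > 1 &&
          min(min_img2(sweep(pos[seq_len(i - 1), , drop = FALSE], 2, p))) <
            0.35^2) next
      pos[i, ] <- p
      placed <- TRUE
      break
    }
    if (!placed)
      stop(sprintf(paste0(
        "ion placement failed for ion %d of %d after %d attempts: ",
        "the requested exclusion distances (0.5 nm from DNA, 0.35 nm ",
        "between ions) exceed the densest allowed packing for this box"),
        i, n_ions, max_attempts))
  }

  structure(
    list(molecule_a = a, molecule_b = b,
         ion_positions = pos, ion_charges = ion_q, box = box),
    class = "system_state")
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf(
    "<system_state> %s(%d) + %s(%d) + %d ions, box %.1f nm, r = %.3f nm\n",
    x$molecule_a$topology, x$molecule_a$n_bp,
    x$molecule_b$topology, x$molecule_b$n_bp,
    length(x$ion_charges), x$box$edge, com_separation(x)))
  invisible(x)
}

#' Total charge of an assembled system (e)
#'
#' @param state A `system_state`.
#' @return Sum of DNA bead and ion charges; 0 for a correctly assembled
#'   system.
#' @export
system_total_charge <- function(state) {
  sum(state$molecule_a$charges) + sum(state$molecule_b$charges) +
    sum(state$ion_charges)
}

#' All particle positions of a system as one matrix
#'
#' Rows are ordered molecule A beads, molecule B beads, ions — the ordering
#' used by trajectory frames and the energy kernels.
#'
#' @param state A `system_state`.
#' @return Numeric matrix with one row per particle (nm).
#' @export
system_positions <- function(state) {
  rbind(state$molecule_a$positions, state$molecule_b$positions,
        state$ion_positions)
}

#' All particle charges of a system (e)
#'
#' @param state A `system_state`.
#' @return Numeric vector aligned with [system_positions()].
#' @export
system_charges <- function(state) {
  c(state$molecule_a$charges, state$molecule_b$charges, state$ion_charges)
}
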