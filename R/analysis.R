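# Conformational and ion-atmosphere observables: gyration tensor and
# principal axes, pair orientation angles, 2D Gaussian KDE, Kabsch
# superposition, RMSF, radial distribution functions and coordination
# numbers.

#' Gyration tensor of a bead cloud
#'
#' The unweighted dyadic `S = (1/N) sum_i r_i (x) r_i` with positions taken
#' in the centre-of-mass frame (all beads carry equal weight; no mass
#' factors).
#'
#' @param positions Numeric matrix, one row per bead (nm).
#' @return Symmetric 3x3 matrix in nm^2.
#' @export
gyration_tensor <- function(positions) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, nrow(positions) >= 1)
  centred <- sweep(positions, 2, colMeans(positions))
  crossprod(centred) / nrow(positions)
}

#' Principal moments and axes of a gyration tensor
#'
#' Eigen-decomposition with eigenvalues sorted descending
#' (lambda1^2 >= lambda2^2 >= lambda3^2) and unit eigenvectors whose first
#' non-zero component is made positive (a deterministic sign convention).
#'
#' @param S Symmetric 3x3 matrix (nm^2); asymmetry beyond 1e-9 is an error.
#' @return An object of class `gyration_spectrum`: `eigenvalues` (nm^2,
#'   descending), `eigenvectors` (columns matched to the eigenvalues),
#'   `r_g` (nm, `sqrt(sum(eigenvalues))`).
#' @export
principal_axes <- function(S) {
  S <- as.matrix(S)
  stopifnot(all(dim(S) == c(3, 3)))
  if (max(abs(S - t(S))) > 1e-9) stop("gyration tensor must be symmetric")
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)  # eigenvalues descending
  vec <- e$vectors
  for (k in 1:3) {
    nz <- which(abs(vec[, k]) > 1e-12)[1]
    if (!is.na(nz) && vec[nz, k] < 0) vec[, k] <- -vec[, k]
  }
  structure(list(eigenvalues = pmax(e$values, 0), eigenvectors = vec,
                 r_g = sqrt(max(sum(e$values), 0))),
            class = "gyration_spectrum")
}

#' Radius of gyration of a bead cloud
#'
#' @param positions Numeric matrix, one row per bead (nm).
#' @return `sqrt(trace(S))` in nm.
#' @export
radius_of_gyration <- function(positions) {
  sqrt(sum(diag(gyration_tensor(positions))))
}

#' Relative orientation angle of a molecule pair
#'
#' The angle `theta = acos(|p1 . p2|)` (degrees) between the selected
#' principal axes of the two molecules' gyration tensors. The absolute value
#' folds the eigenvector sign ambiguity into [0, 90] degrees. For linear
#' pairs the axis of the *largest* eigenvalue (the rod axis) is the natural
#' choice; for ring pairs the axis of the *smallest* eigenvalue — the ring
#' normal, since an ideal ring is flat — so `mode` must be `"largest"` for
#' rods and `"smallest"` for rings.
#'
#' @param a,b Either `molecule_model` objects or bare coordinate matrices.
#' @param mode `"largest"` or `"smallest"`: which principal axis to compare.
#' @param degeneracy_tol Eigenvalue gap below which the selected axis is
#'   ill-defined; such samples carry a `"degenerate"` attribute set `TRUE`.
#' @return Angle in degrees in [0, 90] (attribute `"degenerate"` flags an
#'   ill-conditioned axis).
#' @export
orientation_angle <- function(a, b, mode = c("largest", "smallest"),
                              degeneracy_tol = 1e-12) {
  mode <- match.arg(mode)
  coords <- function(m) if (inherits(m, "molecule_model")) m$positions else m
  pick <- function(pos) {
    spec <- principal_axes(gyration_tensor(coords(pos)))
    k <- if (mode == "largest") 1L else 3L
    gap <- if (mode == "largest") {
      spec$eigenvalues[1] - spec$eigenvalues[2]
    } else {
      spec$eigenvalues[2] - spec$eigenvalues[3]
    }
    list(v = spec$eigenvectors[, k], degenerate = gap < degeneracy_tol)
  }
  pa <- pick(a); pb <- pick(b)
  c_ab <- abs(sum(pa$v * pb$v)) / sqrt(sum(pa$v^2) * sum(pb$v^2))
  ang <- acos(pmin(1, c_ab)) * 180 / pi
  attr(ang, "degenerate") <- pa$degenerate || pb$degenerate
  if (attr(ang, "degenerate"))
    warning("degenerate gyration spectrum: selected axis is ill-defined")
  ang
}

#' Scott's rule bandwidth
#'
#' `h_j = sd_j * n^(-1/(d+4))` per dimension, the standard plug-in choice
#' for a product Gaussian kernel.
#'
#' @param x Numeric vector of samples.
#' @param d Dimensionality of the estimate (2 for the pair (r, theta)).
#' @return Bandwidth (same units as `x`).
#' @export
scott_bandwidth <- function(x, d = 2) {
  stats::sd(x) * length(x)^(-1 / (d + 4))
}

#' 2D Gaussian kernel density estimate on a grid
#'
#' Product-Gaussian KDE of paired observables — here the centre-of-mass
#' separation r and the orientation angle theta — evaluated on a rectangular
#' grid and normalised so the trapezoidal integral over the grid is 1.
#'
#' @param r,theta Equal-length numeric vectors of paired samples (>= 2).
#' @param grid_r,grid_theta Grid coordinates; the defaults cover
#'   [2, 7] nm x [0, 90] degrees at 101 x 91 points.
#' @param bandwidth Optional length-2 vector `(h_r, h_theta)`; default
#'   Scott's rule per dimension. A dimension with zero sample variance
#'   requires an explicit bandwidth.
#' @return An object of class `kde_field`: `grid_r`, `grid_theta`, `density`
#'   (matrix `length(grid_r)` x `length(grid_theta)`), `bandwidth`.
#' @export
kde2d_field <- function(r, theta,
                        grid_r = seq(2, 7, length.out = 101),
                        grid_theta = seq(0, 90, length.out = 91),
                        bandwidth = NULL) {
  stopifnot(length(r) == length(theta), length(r) >= 2)
  if (is.null(bandwidth)) {
    bandwidth <- c(scott_bandwidth(r), scott_bandwidth(theta))
    if (any(!is.finite(bandwidth)) || any(bandwidth <= 0))
      stop(paste("zero sample variance in one dimension:",
                 "supply an explicit bandwidth"))
  }
  stopifnot(length(bandwidth) == 2, all(bandwidth > 0))
  n <- length(r)
  kr <- stats::dnorm(outer(r, grid_r, "-") / bandwidth[1]) / bandwidth[1]
  kt <- stats::dnorm(outer(theta, grid_theta, "-") / bandwidth[2]) / bandwidth[2]
  dens <- crossprod(kr, kt) / n
  # normalise on the grid (trapezoidal) so truncation at the grid edges
  # does not leave mass outside
  z <- trapz2d(grid_r, grid_theta, dens)
  if (z <= 0) stop("degenerate density: no mass on the grid")
  structure(list(grid_r = grid_r, grid_theta = grid_theta,
                 density = dens / z, bandwidth = bandwidth),
            class = "kde_field")
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

trapz2d <- function(gx, gy, f) {
  inner <- apply(f, 1, function(row) trapz(gy, row))
  trapz(gx, inner)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares optimal rotation and translation of `mobile` onto
#' `reference` via SVD of the covariance matrix, with the determinant
#' correction that enforces a proper rotation (no reflection).
#'
#' @param mobile,reference Coordinate matrices of equal size (>= 3 rows).
#' @return A list: `aligned` (transformed mobile coordinates), `rmsd`
#'   (minimised value, nm), `rotation` (3x3), `translation` (length 3).
#' @export
kabsch_align <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)))
    stop("mobile and reference must have identical dimensions")
  stopifnot(ncol(mobile) == 3, nrow(mobile) >= 3)
  cm <- colMeans(mobile); cr <- colMeans(reference)
  x <- sweep(mobile, 2, cm); y <- sweep(reference, 2, cr)
  s <- svd(crossprod(x, y))
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  aligned <- x %*% rot
  aligned <- sweep(aligned, 2, cr, `+`)
  rmsd <- sqrt(mean(rowSums((aligned - reference)^2)))
  list(aligned = aligned, rmsd = rmsd, rotation = rot,
       translation = cr - cm %*% rot)
}

#' Root-mean-square fluctuation profile
#'
#' Each frame is Kabsch-aligned to the reference on the selected sites; the
#' RMSF of site i is `sqrt(mean |r_i - <r_i>|^2)` about the *time-mean*
#' aligned position (the reference only defines the alignment frame, as is
#' standard for fluctuation analysis).
#'
#' @param frames List of coordinate matrices (>= 2 frames).
#' @param reference Reference coordinate matrix (for example the starting
#'   configuration).
#' @param selection Row indices of the sites to align on and report
#'   (default: all rows of `reference`).
#' @return An object of class `rmsf_profile`: data frame with `site_index`
#'   and `rmsf` (nm).
#' @export
rmsf_profile <- function(frames, reference,
                         selection = seq_len(nrow(reference))) {
  stopifnot(length(frames) >= 2)
  reference <- as.matrix(reference)
  ref_sel <- reference[selection, , drop = FALSE]
  aligned <- lapply(frames, function(f) {
    kabsch_align(as.matrix(f)[selection, , drop = FALSE], ref_sel)$aligned
  })
  arr <- simplify2array(aligned)                  # n_sel x 3 x n_frames
  mean_pos <- apply(arr, c(1, 2), mean)
  dev2 <- sweep(arr, c(1, 2), mean_pos)^2
  rmsf <- sqrt(apply(apply(dev2, c(1, 3), sum), 1, mean))
  structure(data.frame(site_index = selection, rmsf = rmsf),
            class = c("rmsf_profile", "data.frame"))
}

#' Radial pair distribution function
#'
#' g(r) between two site groups, averaged over frames: minimum-image pair
#' distances binned and normalised by the ideal-gas shell count
#' `4 pi r^2 dr * rho_b` with `rho_b = N_B / V` (finite-size convention).
#' When the two groups are identical, self-pairs are excluded while `rho_b`
#' keeps the full `N_B / V`; the full-range coordination number then tends
#' to `N_B - 1`.
#'
#' @param frames List of coordinate matrices (all particles).
#' @param group_a,group_b Row indices of the two site groups.
#' @param bin_width Histogram bin width, nm.
#' @param r_max Maximum distance, nm (must be `<= box$edge / 2`).
#' @param box A [simulation_box()].
#' @return An object of class `rdf_curve`: data frame with `r` (bin centres)
#'   and `g`, plus attributes `rho_b` (nm^-3), `n_a`, `n_b`, `bin_width`.
#' @export
rdf <- function(frames, group_a, group_b, bin_width = 0.02, r_max, box) {
  stopifnot(inherits(box, "simulation_box"), length(frames) >= 1)
  if (r_max > box$edge / 2)
    stop("r_max must not exceed half the box edge (minimum image)")
  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  counts <- numeric(length(centers))
  same <- identical(as.integer(group_a), as.integer(group_b))
  edge <- box$edge
  for (f in frames) {
    f <- as.matrix(f)
    pa <- f[group_a, , drop = FALSE]
    pb <- f[group_b, , drop = FALSE]
    d2 <- matrix(0, nrow(pa), nrow(pb))
    for (k in 1:3) {
      dd <- outer(pa[, k], pb[, k], "-")
      dd <- dd - edge * round(dd / edge)
      d2 <- d2 + dd * dd
    }
    if (same) diag(d2) <- Inf
    d <- sqrt(d2[d2 <= r_max^2])
    idx <- findInterval(d, edges, rightmost.closed = TRUE)
    idx[idx == 0] <- 1L
    counts <- counts + tabulate(idx, nbins = length(centers))
  }
  n_a <- length(group_a); n_b <- length(group_b)
  rho_b <- n_b / edge^3
  shell <- 4 * pi * centers^2 * diff(edges)
  g <- counts / (length(frames) * n_a * shell * rho_b)
  structure(data.frame(r = centers, g = g),
            class = c("rdf_curve", "data.frame"),
            rho_b = rho_b, n_a = n_a, n_b = n_b, bin_width = bin_width)
}

#' First-shell boundary of a g(r) curve
#'
#' The first local minimum of g after its first maximum — the conventional
#' integration limit for the first coordination shell. Returns `r_max` of
#' the curve when no interior minimum exists.
#'
#' @param curve An [rdf()] result.
#' @param smooth Running-mean half-width in bins applied before locating
#'   extrema (0 = none).
#' @return Radius in nm.
#' @export
first_shell_radius <- function(curve, smooth = 1L) {
  g <- curve$g; r <- curve$r
  if (smooth > 0) {
    k <- 2 * smooth + 1
    g <- stats::filter(g, rep(1 / k, k), sides = 2)
    g[is.na(g)] <- curve$g[is.na(g)]
  }
  imax <- which.max(g)
  if (imax >= length(g)) return(r[length(r)])
  gg <- g[imax:length(g)]
  dg <- diff(gg)
  turn <- which(dg > 0)[1]  # first uptick after the peak
  if (is.na(turn)) return(r[length(r)])
  r[imax + turn - 1]
}

#' Coordination number from a g(r) curve
#'
#' `n(r_cut) = 4 pi rho_b integral_0^{r_cut} g(r) r^2 dr` by the trapezoidal
#' rule; with `r_cut` at the first minimum after the first peak this is the
#' first-shell coordination number.
#'
#' @param curve An [rdf()] result.
#' @param r_cut Integration limit, nm (default: [first_shell_radius()]).
#' @return Coordination number (dimensionless).
#' @export
coordination_number <- function(curve, r_cut = first_shell_radius(curve)) {
  r <- curve$r; g <- curve$g
  if (r_cut < 0 || r_cut > r[length(r)] + attr(curve, "bin_width") / 2)
    stop("r_cut outside the range of the g(r) curve")
  keep <- r < r_cut
  # integrate from 0 (flat extrapolation below the first bin centre, where
  # the r^2 weight makes the contribution negligible) to exactly r_cut
  # (linear interpolation of g at the endpoint)
  g_cut <- stats::approx(r, g, xout = r_cut, rule = 2)$y
  xs <- c(0, r[keep], r_cut)
  ys <- c(g[1], g[keep], g_cut) * xs^2
  rho_b <- attr(curve, "rho_b")
  4 * pi * rho_b * trapz(xs, ys)
}

#' Orientation samples from a window record
#'
#' Computes the (r, theta) pair for every stored frame of a window record:
#' r from the two molecules' centroids, theta from [orientation_angle()]
#' with the topology-appropriate eigen-mode.
#'
#' @param record A [run_window()] result with stored frames.
#' @param mode Eigen-mode passed to [orientation_angle()]; the default picks
#'   `"smallest"` for rings and `"largest"` for linear molecules from the
#'   record's final state.
#' @return Data frame with columns `r` (nm) and `theta` (degrees).
#' @export
orientation_samples <- function(record, mode = NULL) {
  stopifnot(inherits(record, "window_record"))
  if (length(record$frames) == 0) stop("window record holds no frames")
  nA <- record$n_dna[1]; nB <- record$n_dna[2]
  if (is.null(mode)) {
    mode <- if (!is.null(record$final_state) &&
                record$final_state$molecule_a$topology == "ring")
      "smallest" else "largest"
  }
  res <- lapply(record$frames, function(f) {
    f <- as.matrix(f)
    pa <- f[seq_len(nA), , drop = FALSE]
    pb <- f[nA + seq_len(nB), , drop = FALSE]
    d <- colMeans(pa) - colMeans(pb)
    th <- suppressWarnings(orientation_angle(pa, pb, mode = mode))
    c(r = sqrt(sum(d * d)), theta = as.numeric(th))
  })
  as.data.frame(do.call(rbind, res))
}
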