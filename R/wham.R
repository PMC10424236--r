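# Weighted histogram analysis method for distance-coordinate umbrella
# sampling. The self-consistent equations are iterated in log space
# (log-sum-exp) so large bias energies at the histogram edges cannot
# underflow:
#   P(x_b) = sum_i n_i(x_b) / sum_i N_i exp[(f_i - w_i(x_b)) / kT]
#   exp(-f_i / kT) = sum_b P(x_b) exp(-w_i(x_b) / kT)
# No radial-entropy (2 kT ln r) correction is applied: the output is the
# standard distance-WHAM V_eff(r), so for two isolated particles it equals
# the pair potential plus the -2 kT ln(r / r_ref) radial-measure term.

#' Default PMF bin edges
#'
#' 0.05 nm bins over [1.8, 7.2] nm — half the production window spacing,
#' fine enough to resolve peak positions at 0.1 nm precision.
#'
#' @return Numeric vector of bin edges.
#' @export
default_pmf_edges <- function() seq(1.8, 7.2, by = 0.05)

#' Histogram one umbrella window's reaction-coordinate series
#'
#' Left-closed right-open binning; a sample exactly on an interior edge goes
#' to the right bin. Samples outside the bin range are an error (never
#' silently clipped).
#'
#' @param record A [window_record()].
#' @param bin_edges Strictly increasing bin edges, nm (shared by all windows
#'   of a WHAM set).
#' @return An object of class `window_histogram`: `window`, `bin_edges`,
#'   `counts`, `n_total`.
#' @export
histogram_window <- function(record, bin_edges = default_pmf_edges()) {
  stopifnot(inherits(record, "window_record"))
  x <- record$rc_series
  if (length(x) == 0) stop("empty reaction-coordinate series")
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("bin_edges must be strictly increasing")
  lo <- bin_edges[1]; hi <- bin_edges[length(bin_edges)]
  bad <- x < lo | x >= hi
  if (any(bad))
    stop(sprintf(
      "sample(s) outside the histogram range [%g, %g): first offender %g",
      lo, hi, x[which(bad)[1]]))
  idx <- findInterval(x, bin_edges, rightmost.closed = FALSE, left.open = FALSE)
  counts <- tabulate(idx, nbins = length(bin_edges) - 1)
  structure(list(window = record$window, bin_edges = bin_edges,
                 counts = as.integer(counts), n_total = length(x)),
            class = "window_histogram")
}

check_shared_bins <- function(histograms) {
  stopifnot(length(histograms) >= 1)
  edges <- histograms[[1]]$bin_edges
  for (h in histograms) {
    stopifnot(inherits(h, "window_histogram"))
    if (!isTRUE(all.equal(h$bin_edges, edges)))
      stop("all histograms must share the same bin edges")
  }
  edges
}

logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Solve the WHAM self-consistent equations
#'
#' Iterates the coupled equations for the per-window free energies `f_i`
#' (gauge-fixed so the first window has `f = 0`) and the unbiased density
#' until `max |delta f_i| < tol * kT`. Bins with zero total counts get zero
#' density and are flagged. Evaluation is in log space throughout.
#'
#' @param histograms List of [histogram_window()] results with shared bins.
#' @param temperature Temperature in K.
#' @param tol Convergence tolerance on `max |delta f|` in units of kT.
#' @param max_iter Maximum number of iterations.
#' @return A list: `f` (kJ/mol, per window), `density` (normalised over
#'   occupied bins), `bin_centers`, `occupied` (logical), `n_iter`,
#'   `residual` (kT units), `residual_history` (last iterations).
#' @export
solve_wham <- function(histograms, temperature = 300, tol = 1e-7,
                       max_iter = 1e5) {
  edges <- check_shared_bins(histograms)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  n_bin <- length(centers)
  n_win <- length(histograms)
  kbt <- kT(temperature)

  counts <- vapply(histograms, function(h) as.numeric(h$counts),
                   numeric(n_bin))                       # n_bin x n_win
  counts <- matrix(counts, nrow = n_bin)
  N_i <- colSums(counts)
  n_b <- rowSums(counts)
  occupied <- n_b > 0
  if (!any(occupied)) stop("all histogram bins are empty")

  # zero-overlap check: windows sorted by center must chain through shared
  # occupied bins
  if (n_win > 1) {
    ord <- order(vapply(histograms, function(h) h$window$center, 0))
    for (k in seq_len(n_win - 1)) {
      a <- counts[, ord[k]] > 0; b <- counts[, ord[k + 1]] > 0
      if (!any(a & b))
        stop(sprintf(
          "zero histogram overlap between windows centred at %g and %g nm",
          histograms[[ord[k]]]$window$center,
          histograms[[ord[k + 1]]]$window$center))
    }
  }

  # bias energies w_i(x_b) / kT
  w <- vapply(histograms,
              function(h) bias_energy(h$window, centers) / kbt,
              numeric(n_bin))
  w <- matrix(w, nrow = n_bin)

  log_nb <- ifelse(occupied, log(n_b), -Inf)
  log_Ni <- log(N_i)
  g <- numeric(n_win)  # f_i / kT
  resid_hist <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # log denominator per bin: logsumexp_i [log N_i + g_i - w_ib]
    denom <- logsumexp_rows(sweep(-w, 2, log_Ni + g, `+`))
    log_p <- log_nb - denom
    # new g_i = -log sum_b exp(log_p_b - w_ib)
    lp <- log_p[occupied]
    g_new <- -apply(-w[occupied, , drop = FALSE] + lp, 2, function(col) {
      mx <- max(col); mx + log(sum(exp(col - mx)))
    })
    g_new <- g_new - g_new[1]  # gauge: f_1 = 0
    resid <- max(abs(g_new - g))
    resid_hist <- c(resid_hist, resid)
    g <- g_new
    if (resid < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop(sprintf("WHAM did not converge in %d iterations (last residual %g kT)",
                 as.integer(max_iter), resid_hist[length(resid_hist)]))
  tail_res <- utils::tail(resid_hist, 10)
  if (length(tail_res) >= 2 && any(diff(tail_res) > 0))
    warning("WHAM residual was not monotonically decreasing over the last iterations")

  denom <- logsumexp_rows(sweep(-w, 2, log_Ni + g, `+`))
  log_p <- log_nb - denom
  p <- exp(log_p - max(log_p[occupied]))
  p[!occupied] <- 0
  p <- p / sum(p)
  list(f = g * kbt, density = p, bin_centers = centers, occupied = occupied,
       n_iter = it, residual = resid_hist[length(resid_hist)],
       residual_history = utils::tail(resid_hist, 10))
}

#' Effective potential from an unbiased density
#'
#' `V_eff(b) = -kT ln density(b)`, shifted so the bin containing
#' `reference_r` is exactly zero (the production convention uses
#' `reference_r = 7.0` nm). Empty bins are `NA`, never interpolated. No
#' Jacobian/entropy correction is applied.
#'
#' @param density Non-negative per-bin density.
#' @param bin_centers Bin centres, nm.
#' @param reference_r Reference separation defined to zero, nm.
#' @param temperature Temperature in K.
#' @param stderr Optional per-bin standard errors (kJ/mol).
#' @return An object of class `pmf_profile`: `bin_centers`, `v_eff`,
#'   `stderr`, `reference_r`.
#' @export
pmf_from_density <- function(density, bin_centers, reference_r = 7.0,
                             temperature = 300, stderr = NULL) {
  if (length(density) != length(bin_centers))
    stop("density and bin_centers must have equal length")
  if (any(density < 0)) stop("density must be non-negative")
  ref_bin <- which.min(abs(bin_centers - reference_r))
  if (density[ref_bin] <= 0)
    stop(sprintf("reference bin at r = %g nm is empty", reference_r))
  kbt <- kT(temperature)
  v <- ifelse(density > 0, -kbt * log(density), NA_real_)
  v <- v - v[ref_bin]
  structure(list(bin_centers = bin_centers, v_eff = v, stderr = stderr,
                 reference_r = reference_r),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  ok <- is.finite(x$v_eff)
  cat(sprintf(
    "<pmf_profile> %d bins (%d occupied), r in [%.2f, %.2f] nm, zero at %.1f nm\n",
    length(x$v_eff), sum(ok), min(x$bin_centers), max(x$bin_centers),
    x$reference_r))
  invisible(x)
}

#' Reconstruct the effective potential from a set of window records
#'
#' Convenience wrapper: histogram every window on shared bins, solve WHAM,
#' and convert to a referenced effective potential.
#'
#' @param records List of [window_record()] objects.
#' @param bin_edges Shared bin edges, nm.
#' @param reference_r Reference separation, nm.
#' @param temperature Temperature, K.
#' @param tol,max_iter Passed to [solve_wham()].
#' @return A `pmf_profile` with the WHAM solution attached as attribute
#'   `"wham"`.
#' @export
pmf_from_records <- function(records, bin_edges = default_pmf_edges(),
                             reference_r = 7.0, temperature = 300,
                             tol = 1e-7, max_iter = 1e5) {
  hists <- lapply(records, histogram_window, bin_edges = bin_edges)
  sol <- solve_wham(hists, temperature = temperature, tol = tol,
                    max_iter = max_iter)
  prof <- pmf_from_density(sol$density, sol$bin_centers,
                           reference_r = reference_r,
                           temperature = temperature)
  attr(prof, "wham") <- sol
  prof
}

#' Histogram overlap between adjacent windows
#'
#' For each adjacent window pair (sorted by centre) the summed minimum of the
#' two normalised histograms, a number in [0, 1]; pairs below 0.05 are
#' flagged — WHAM cannot bridge windows that barely overlap.
#'
#' @param histograms List of [histogram_window()] results (>= 2) with shared
#'   bins.
#' @return Data frame with `center_left`, `center_right`, `overlap`,
#'   `flagged`.
#' @export
overlap_diagnostic <- function(histograms) {
  if (length(histograms) < 2) stop("need at least 2 histograms")
  check_shared_bins(histograms)
  ord <- order(vapply(histograms, function(h) h$window$center, 0))
  histograms <- histograms[ord]
  res <- lapply(seq_len(length(histograms) - 1), function(k) {
    a <- histograms[[k]]; b <- histograms[[k + 1]]
    ov <- sum(pmin(a$counts / a$n_total, b$counts / b$n_total))
    data.frame(center_left = a$window$center, center_right = b$window$center,
               overlap = ov, flagged = ov < 0.05)
  })
  do.call(rbind, res)
}

#' Bootstrap uncertainty for the effective potential
#'
#' Resamples each window's reaction-coordinate series with replacement,
#' reruns WHAM per replicate, and reports the per-bin standard deviation
#' across replicates as the standard error. Deterministic under `seed`.
#'
#' @param records List of [window_record()] objects.
#' @param n_boot Number of bootstrap replicates (>= 2).
#' @param seed Integer seed.
#' @param resample Set `FALSE` to rerun on the original data (degenerate
#'   replicates; useful only to verify that the spread is then zero).
#' @inheritParams pmf_from_records
#' @return A `pmf_profile` whose `stderr` field holds the bootstrap standard
#'   errors; the point estimate is from the full data.
#' @export
bootstrap_pmf <- function(records, n_boot = 20, seed = 1L,
                          bin_edges = default_pmf_edges(), reference_r = 7.0,
                          temperature = 300, tol = 1e-7, max_iter = 1e5,
                          resample = TRUE) {
  if (n_boot < 2) stop("n_boot must be at least 2")
  full <- pmf_from_records(records, bin_edges, reference_r, temperature,
                           tol, max_iter)
  set.seed(as.integer(seed))
  reps <- matrix(NA_real_, length(full$v_eff), n_boot)
  for (b in seq_len(n_boot)) {
    rb <- lapply(records, function(rec) {
      x <- rec$rc_series
      if (resample) x <- x[sample.int(length(x), replace = TRUE)]
      window_record(rec$window, x, seed = rec$seed)
    })
    reps[, b] <- pmf_from_records(rb, bin_edges, reference_r, temperature,
                                  tol, max_iter)$v_eff
  }
  full$stderr <- apply(reps, 1, stats::sd)
  full
}
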