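#' Exponential-averaging interaction free energy
#'
#' Delta G = -kT log(mean(exp(-U / kT))) with the ideal gas as reference
#' state, computed through a max-shift (log-sum-exp) so arbitrarily large
#' interaction energies cannot overflow.  kB = 0.0019872041 kcal/(mol K).
#'
#' @param series an [energy_series()] (values in kcal/mol).
#' @return Delta G in kcal/mol.
#' @examples
#' s <- energy_series(c(-10, -10, -10), temperature = 300)
#' exp_avg_free_energy(s)  # exactly -10
#' @export
exp_avg_free_energy <- function(series) {
  stopifnot(inherits(series, "energy_series"))
  kT <- .KB_KCAL * series$temperature
  x <- -series$values / kT
  m <- max(x)
  lse <- m + log(mean(exp(x - m)))
  -kT * lse
}

#' Block-averaged free energy estimate
#'
#' Splits the (by default, last half of the) series into `n_blocks` equal
#' contiguous blocks, applies the exponential average per block, and reports
#' the mean of the block values with their SD as the error - the standard
#' remedy for long-timescale drift in interaction-energy series.
#'
#' @param series an [energy_series()].
#' @param n_blocks number of blocks (>= 2).
#' @param use_last_half analyse only the last half of the series.
#' @return object of class `free_energy`: `delta_g`, `error` (kcal/mol),
#'   `n_blocks`, `temperature`, `n_used`, `state`.
#' @export
block_free_energy <- function(series, n_blocks = 5, use_last_half = TRUE) {
  stopifnot(inherits(series, "energy_series"))
  if (n_blocks < 2) stop("need at least 2 blocks")
  v <- series$values
  if (use_last_half) v <- v[(floor(length(v) / 2) + 1):length(v)]
  if (length(v) < 2 * n_blocks)
    stop("series too short: need at least 2 points per block after halving")
  idx <- cut(seq_along(v), n_blocks, labels = FALSE)
  dg <- vapply(seq_len(n_blocks), function(b)
    exp_avg_free_energy(energy_series(v[idx == b],
                                      frame_ps = series$frame_ps,
                                      temperature = series$temperature)),
    numeric(1))
  structure(list(delta_g = mean(dg), error = stats::sd(dg),
                 block_values = dg, n_blocks = n_blocks,
                 temperature = series$temperature, n_used = length(v),
                 state = series$state), class = "free_energy")
}

#' @export
print.free_energy <- function(x, ...) {
  cat(sprintf("Delta G = %.4g +/- %.3g kcal/mol (%d blocks, %d frames, T = %g K%s)\n",
              x$delta_g, x$error, x$n_blocks, x$n_used, x$temperature,
              if (is.null(x$state)) "" else paste0(", state ", x$state)))
  invisible(x)
}

#' Temperature difference of interaction free energies
#'
#' Delta Delta G = Delta G(T1) - Delta G(T2) with errors combined in
#' quadrature.  Estimates must carry the same state/composition label; the
#' difference is only meaningful between simulations of identical systems.
#'
#' @param est_T1,est_T2 `free_energy` objects.
#' @return list with `value` and `error`, kcal/mol.
#' @export
delta_delta_g <- function(est_T1, est_T2) {
  stopifnot(inherits(est_T1, "free_energy"), inherits(est_T2, "free_energy"))
  if (!identical(est_T1$state, est_T2$state))
    stop("state/composition labels differ; refusing to difference")
  list(value = est_T1$delta_g - est_T2$delta_g,
       error = sqrt(est_T1$error^2 + est_T2$error^2))
}

#' Pressure-volume contribution
#'
#' p V N_A in kJ/mol; 1 bar nm^3 = 0.0602214 kJ/mol.  For simulation boxes
#' of roughly 1545-1594 nm^3 at the 1 bar reference pressure this gives the
#' 93-96 kJ/mol contribution that is negligible next to the interaction
#' energies.
#'
#' @param pressure_bar pressure, bar (> 0).
#' @param volume_nm3 box volume, nm^3 (> 0).
#' @return kJ/mol.
#' @export
pv_term <- function(pressure_bar, volume_nm3) {
  if (any(pressure_bar <= 0) || any(volume_nm3 <= 0))
    stop("pressure and volume must be positive")
  pressure_bar * volume_nm3 * 0.0602214076
}

#' Convert kJ/mol to kcal/mol (and back)
#' @param x energies.
#' @return converted energies.
#' @export
kj_to_kcal <- function(x) x / 4.184

#' @rdname kj_to_kcal
#' @export
kcal_to_kj <- function(x) x * 4.184

#' Radial distribution of points around a reference set
#'
#' Histograms the minimum distance from each point to the reference set and
#' normalises shell-wise by the bulk density (annular area in 2D, shell
#' volume in 3D), as used for e.g. lipid headgroups around a protein in one
#' leaflet.  With a multi-point reference the shell normalisation treats the
#' reference as a single centre and is approximate near its extent.
#'
#' @param points n x d matrix of coordinates (d = 2 or 3), nm.
#' @param reference_points m x d matrix, nm.
#' @param r_max histogram range, nm.
#' @param n_bins number of bins.
#' @param box_measure box area (2D) or volume (3D) for the bulk density.
#' @param dimensionality 2 or 3.
#' @return object of class `rdf_profile`: `r` (bin centres), `g`,
#'   `bulk_density`.
#' @export
radial_distribution <- function(points, reference_points, r_max, n_bins = 50,
                                box_measure, dimensionality = c(2, 3)) {
  dimensionality <- match.arg(as.character(dimensionality[1]), c("2", "3"))
  dims <- as.integer(dimensionality)
  points <- as.matrix(points)
  reference_points <- matrix(as.matrix(reference_points), ncol = ncol(points))
  if (nrow(points) == 0 || nrow(reference_points) == 0)
    stop("point sets must be nonempty")
  if (box_measure <= 0) stop("box measure must be positive")
  if (r_max > 0.5 * box_measure^(1 / dims) * 2)
    warning("r_max exceeds half the box extent; tail normalisation unreliable")
  dmin <- apply(points, 1, function(p)
    sqrt(min(colSums((t(reference_points) - p)^2))))
  breaks <- seq(0, r_max, length.out = n_bins + 1)
  counts <- graphics::hist(dmin[dmin <= r_max], breaks = breaks,
                           plot = FALSE)$counts
  rho <- nrow(points) / box_measure
  shell <- if (dims == 2) pi * diff(breaks^2) else (4 / 3) * pi * diff(breaks^3)
  g <- counts / (rho * shell)
  structure(list(r = (head(breaks, -1) + tail(breaks, -1)) / 2, g = g,
                 bulk_density = rho, dimensionality = dims),
            class = "rdf_profile")
}

#' @export
print.rdf_profile <- function(x, ...) {
  cat(sprintf("RDF profile: %d bins to %.2f nm (%dD), bulk density %.3g\n",
              length(x$r), max(x$r), x$dimensionality, x$bulk_density))
  invisible(x)
}

#' @export
plot.rdf_profile <- function(x, ..., xlab = "r (nm)", ylab = "g(r)") {
  graphics::plot(x$r, x$g, type = "l", xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = 1, lty = 2, col = "grey50")
  invisible(x)
}

#' Read an energy series from delimited text (frame, energy)
#'
#' @param file two-column delimited text: frame index (or time) and energy.
#' @param unit "kcal" or "kj" - input energy unit; stored as kcal/mol.
#' @param temperature temperature, K.
#' @param frame_ps frame spacing, ps.
#' @param state optional state label.
#' @return an `energy_series`.
#' @export
read_energy_series <- function(file, unit = c("kcal", "kj"),
                               temperature = 292.15, frame_ps = 100,
                               state = NULL) {
  unit <- match.arg(unit)
  m <- as.matrix(read.table(file))
  u <- m[, ncol(m)]
  if (unit == "kj") u <- kj_to_kcal(u)
  energy_series(u, frame_ps = frame_ps, temperature = temperature,
                state = state)
}
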