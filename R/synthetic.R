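#' Gaussian-mixture ground-truth distance distribution
#'
#' Builds a known P(r) from Gaussian components, the shape observed for the
#' two cap conformations of a dimeric K2P channel: a short, broad component
#' (non-swapped, near 3.3 nm) and a long, narrow one (swapped, near 5 nm).
#'
#' @param components data.frame with columns `mean` (nm), `sd` (nm), `weight`
#'   (fractions summing to 1).
#' @param axis distance axis from [distance_axis()].
#' @return a `ddist`.
#' @examples
#' gt <- make_ground_truth(
#'   data.frame(mean = c(3.3, 5.0), sd = c(0.5, 0.3), weight = c(0.43, 0.57)))
#' @export
make_ground_truth <- function(components, axis = distance_axis()) {
  stopifnot(is.data.frame(components),
            all(c("mean", "sd", "weight") %in% names(components)))
  if (any(components$weight < 0)) stop("weights must be non-negative")
  if (abs(sum(components$weight) - 1) > 1e-6) stop("weights must sum to 1")
  if (any(components$sd <= 0)) stop("component sd must be positive")
  if (any(components$mean < min(axis) | components$mean > max(axis)))
    stop("component means must lie inside the distance axis")
  dens <- rep(0, length(axis))
  for (i in seq_len(nrow(components)))
    dens <- dens + components$weight[i] *
      dnorm(axis, components$mean[i], components$sd[i])
  distance_distribution(axis, dens, normalize = TRUE)
}

#' Specification of one simulated dipolar trace
#'
#' @param t_max trace length, microseconds (capped at 10; experimental traces
#'   here reach up to 7.5 us, the limit set by transverse dephasing).
#' @param dt time step, microseconds.
#' @param lambda modulation depth.
#' @param k,d background rate and stretch dimensionality.
#' @param noise_sd white Gaussian noise level as a fraction of V0.
#' @param V0 trace scale.
#' @param seed RNG seed for the noise.
#' @param label optional trace label.
#' @return a `trace_spec` list.
#' @export
trace_spec <- function(t_max, dt = 0.016, lambda = 0.3, k = 0.05, d = 3,
                       noise_sd = 0.005, V0 = 1, seed = 1, label = NULL) {
  if (dt <= 0 || dt >= t_max) stop("need 0 < dt < t_max")
  if (t_max > 10) stop("t_max capped at 10 us")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (lambda <= 0 || lambda >= 1) stop("lambda must lie in (0, 1)")
  structure(list(t_max = t_max, dt = dt, lambda = lambda, k = k, d = d,
                 noise_sd = noise_sd, V0 = V0, seed = as.integer(seed),
                 label = label %||% sprintf("t%gus", t_max)),
            class = "trace_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a single DEER trace with known ground truth
#'
#' Forward model plus white Gaussian noise on the real channel; deterministic
#' given the seed.
#'
#' @param P ground-truth `ddist`.
#' @param spec a [trace_spec()].
#' @return a `deer_trace`: list with `t` (us), `V`, `sigma` (noise level),
#'   `label`, and `meta` recording the generating parameters.
#' @export
simulate_trace <- function(P, spec) {
  stopifnot(inherits(P, "ddist"), inherits(spec, "trace_spec"))
  t <- seq(0, spec$t_max, by = spec$dt)
  clean <- dipolar_signal(P, t, spec$lambda, spec$k, spec$d, spec$V0)
  noise <- if (spec$noise_sd > 0)
    with_seed(spec$seed, rnorm(length(t), 0, spec$noise_sd * spec$V0))
  else 0
  structure(list(t = t, V = clean + noise, sigma = spec$noise_sd * spec$V0,
                 label = spec$label, meta = unclass(spec)),
            class = "deer_trace")
}

#' @export
print.deer_trace <- function(x, ...) {
  cat(sprintf("DEER trace '%s': %d points, t in [0, %.3f] us, noise sigma %.4g\n",
              x$label %||% "", length(x$t), max(x$t), x$sigma %||% NA))
  invisible(x)
}

#' Simulate a set of traces sharing one ground truth
#'
#' Emulates the experimental practice of measuring one sample over several
#' dipolar evolution windows (up to 4 traces per sample) and analysing them
#' globally.
#'
#' @param P ground-truth `ddist`.
#' @param specs list of 1-6 [trace_spec()] objects.
#' @return a `deer_traceset`: list of `deer_trace` with attribute `truth`.
#' @export
simulate_trace_set <- function(P, specs) {
  if (!is.list(specs) || length(specs) == 0) stop("need at least one trace spec")
  if (inherits(specs, "trace_spec")) specs <- list(specs)
  if (length(specs) > 6) stop("at most 6 traces per sample")
  traces <- lapply(specs, function(s) simulate_trace(P, s))
  structure(traces, class = "deer_traceset", truth = P)
}

#' @export
print.deer_traceset <- function(x, ...) {
  cat(sprintf("DEER trace set: %d trace(s), t_max = %s us\n", length(x),
              paste(vapply(x, function(tr) max(tr$t), numeric(1)), collapse = "/")))
  invisible(x)
}

#' Write / read a trace set as delimited text with a metadata sidecar
#'
#' Each trace becomes a two-column file (time us, signal); a YAML sidecar
#' records per-trace generating parameters so ground truth round-trips with
#' the data.
#'
#' @param ts a `deer_traceset`.
#' @param dir output directory (created if needed).
#' @param name basename for the files.
#' @return invisibly, the file paths written.
#' @export
write_trace_set <- function(ts, dir, name = "sample") {
  stopifnot(inherits(ts, "deer_traceset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(ts))
  meta <- list()
  for (i in seq_along(ts)) {
    f <- file.path(dir, sprintf("%s_trace%d.dat", name, i))
    m <- cbind(ts[[i]]$t, ts[[i]]$V)
    write.table(format(m, digits = 17, scientific = TRUE, trim = TRUE),
                f, row.names = FALSE, col.names = FALSE, quote = FALSE)
    files[i] <- f
    meta[[sprintf("trace%d", i)]] <- c(ts[[i]]$meta,
                                       list(sigma = ts[[i]]$sigma))
  }
  yaml::write_yaml(meta, file.path(dir, sprintf("%s_meta.yml", name)))
  invisible(c(files, file.path(dir, sprintf("%s_meta.yml", name))))
}

#' @rdname write_trace_set
#' @param name basename used when writing.
#' @export
read_trace_set <- function(dir, name = "sample") {
  metafile <- file.path(dir, sprintf("%s_meta.yml", name))
  if (!file.exists(metafile)) stop("metadata sidecar not found: ", metafile)
  meta <- yaml::read_yaml(metafile)
  traces <- vector("list", length(meta))
  for (i in seq_along(meta)) {
    f <- file.path(dir, sprintf("%s_trace%d.dat", name, i))
    m <- as.matrix(read.table(f))
    traces[[i]] <- structure(
      list(t = m[, 1], V = m[, 2], sigma = meta[[i]]$sigma,
           label = meta[[i]]$label, meta = meta[[i]]),
      class = "deer_trace")
  }
  structure(traces, class = "deer_traceset")
}

#' Packaged study fixtures
#'
#' Named ground-truth conditions used throughout the package: component means
#' and widths are the in-silico predictions for the two cap states of the
#' K2P channel dimer (non-swapped 3.3 nm / SD 0.5 nm; swapped 5.0 nm /
#' SD 0.3 nm), and the component weights encode the fitted populations at
#' 19 C ("exp19C": swapped 57%) and 40 C ("exp40C": swapped 66%).  The trace
#' block gives the default simulation conditions (4 evolution windows up to
#' 7.5 us, modulation depth 0.3, 3D background k = 0.05, noise 0.005 of V0).
#'
#' @param name fixture name, "exp19C" or "exp40C".
#' @return list with `components` (data.frame), `trace` defaults and
#'   `quantify` settings.
#' @export
deer_fixture <- function(name = c("exp19C", "exp40C")) {
  name <- match.arg(name)
  cfg <- yaml::read_yaml(system.file("extdata", "fixtures.yml",
                                     package = "deerpop"))
  fx <- cfg[[name]]
  fx$components <- do.call(rbind, lapply(fx$components, as.data.frame))
  fx
}

#' Simulate the standard four-trace set for a packaged fixture
#'
#' @param name fixture name (see [deer_fixture()]).
#' @param seed base RNG seed; trace i uses `seed * 10 + i` so different
#'   windows carry independent noise.
#' @param axis distance axis for the ground truth.
#' @return a `deer_traceset`.
#' @export
simulate_fixture <- function(name = c("exp19C", "exp40C"), seed = 1,
                             axis = distance_axis()) {
  fx <- deer_fixture(name)
  gt <- make_ground_truth(fx$components, axis)
  tr <- fx$trace
  specs <- lapply(seq_along(tr$t_max), function(i)
    trace_spec(t_max = tr$t_max[[i]], dt = tr$dt, lambda = tr$lambda,
               k = tr$k, d = tr$d, noise_sd = tr$noise_sd,
               seed = seed * 10 + i))
  simulate_trace_set(gt, specs)
}

#' Autocorrelated (AR(1)) synthetic interaction-energy series
#'
#' Stand-in for MD interaction-energy output: a stationary AR(1) process
#' with given marginal mean and SD and lag-1 autocorrelation
#' exp(-1/autocorr_time).
#'
#' @param mean marginal mean, kcal/mol.
#' @param sd marginal SD, kcal/mol (>= 0).
#' @param autocorr_time correlation time in frames.
#' @param n number of frames (>= 2).
#' @param temperature simulation temperature, K.
#' @param frame_ps frame spacing, ps (metadata only).
#' @param seed RNG seed.
#' @return an `energy_series`: list with `values`, `frame_ps`, `temperature`.
#' @export
simulate_energy_series <- function(mean, sd, autocorr_time = 10, n = 1000,
                                   temperature = 292.15, frame_ps = 100,
                                   seed = 1) {
  if (sd < 0) stop("sd must be non-negative")
  if (n < 2) stop("need at least two frames")
  if (temperature <= 0) stop("temperature must be positive")
  phi <- exp(-1 / autocorr_time)
  x <- with_seed(seed, {
    e <- rnorm(n, 0, sd * sqrt(1 - phi^2))
    x <- numeric(n)
    x[1] <- rnorm(1, 0, max(sd, .Machine$double.eps))
    if (sd == 0) x[1] <- 0
    for (i in 2:n) x[i] <- phi * x[i - 1] + e[i]
    x
  })
  energy_series(mean + x, frame_ps = frame_ps, temperature = temperature)
}

#' Energy series container
#' @param values energies per frame, kcal/mol.
#' @param frame_ps frame spacing, ps.
#' @param temperature temperature, K.
#' @param state optional state/composition label (used to guard temperature
#'   differences).
#' @return an `energy_series`.
#' @export
energy_series <- function(values, frame_ps = 100, temperature = 292.15,
                          state = NULL) {
  if (length(values) < 2) stop("energy series needs at least two frames")
  if (any(!is.finite(values))) stop("energy values must be finite")
  if (temperature <= 0) stop("temperature must be positive")
  structure(list(values = as.numeric(values), frame_ps = frame_ps,
                 temperature = temperature, state = state),
            class = "energy_series")
}
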