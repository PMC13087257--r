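#' Read a dipolar trace from delimited text
#'
#' Accepts two columns (time, real signal) or three (time, real, imaginary).
#' Time units are auto-detected (values above 100 are taken as ns and
#' converted to us) unless given.  The trace is zero-aligned, scaled so its
#' first point is 1, and its noise level estimated from the high-frequency
#' residual of a moving polynomial (Savitzky-Golay) fit.  If an imaginary
#' channel is present it is discarded after a phase rotation minimising its
#' RMS.
#'
#' @param file path to a delimited text file.
#' @param time_unit "auto", "us" or "ns".
#' @param label optional trace label (defaults to the file name).
#' @return a `deer_trace`.
#' @export
read_trace <- function(file, time_unit = c("auto", "us", "ns"), label = NULL) {
  time_unit <- match.arg(time_unit)
  lines <- readLines(file)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*[#%;]", lines))
  if (length(keep) == 0) stop("no data rows in ", file)
  rows <- strsplit(trimws(lines[keep]), "[,;[:space:]]+")
  ncol <- length(rows[[1]])
  if (!ncol %in% c(2, 3))
    stop("expected 2 or 3 columns, found ", ncol, " at line ", keep[1])
  m <- matrix(NA_real_, length(rows), ncol)
  for (i in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(rows[[i]]))
    if (length(v) != ncol || any(is.na(v)))
      stop("parse error at line ", keep[i], " of ", file)
    m[i, ] <- v
  }
  if (nrow(m) < 50) stop("trace has fewer than 50 points")
  t <- m[, 1]
  if (any(diff(t) <= 0)) stop("time column is not strictly increasing")
  if (time_unit == "ns" || (time_unit == "auto" && max(t) > 100))
    t <- t / 1000
  V <- m[, 2]
  if (ncol == 3) {
    z <- complex(real = m[, 2], imaginary = m[, 3])
    obj <- function(ph) sum(Im(z * exp(1i * ph))^2)
    ph <- optimize(obj, c(-pi, pi))$minimum
    zr <- z * exp(1i * ph)
    if (sum(Re(zr)) < 0) zr <- -zr
    V <- Re(zr)
  }
  t <- t - t[1]
  V <- V / V[1]
  structure(list(t = t, V = V, sigma = estimate_noise(V),
                 label = label %||% basename(file), meta = list(file = file)),
            class = "deer_trace")
}

#' Estimate the noise level of a trace
#'
#' Standard deviation (robust, MAD-based) of the residual after a moving
#' cubic Savitzky-Golay fit; the dipolar oscillation is smooth on the scale
#' of the window, so the residual is dominated by detector noise.
#'
#' @param V signal values.
#' @param window odd window length for the moving fit.
#' @return noise SD estimate.
#' @export
estimate_noise <- function(V, window = 15) {
  n <- length(V)
  window <- min(window, if (n %% 2 == 0) n - 1 else n)
  if (window %% 2 == 0) window <- window - 1
  if (window < 5) return(stats::sd(V))
  sm <- signal::sgolayfilt(V, p = 3, n = window)
  stats::mad(V - sm)
}

#' Remove trailing points from a trace
#'
#' The final points of long traces can carry "2 + 1" pulse-overlap
#' artefacts; this removes them while keeping at least 50 points.
#'
#' @param trace a `deer_trace`.
#' @param n_points number of trailing points to drop (>= 0).
#' @return the truncated `deer_trace`; `meta$truncated` records `n_points`.
#' @export
truncate_end <- function(trace, n_points) {
  stopifnot(inherits(trace, "deer_trace"))
  n <- length(trace$t)
  if (n_points < 0 || n_points >= n - 50 + 1)
    stop("n_points must satisfy 0 <= n_points < length - 50")
  if (n_points == 0) return(trace)
  idx <- seq_len(n - n_points)
  trace$t <- trace$t[idx]
  trace$V <- trace$V[idx]
  trace$meta$truncated <- (trace$meta$truncated %||% 0) + n_points
  trace
}

# ---- internal problem assembly ------------------------------------------

.as_traceset <- function(traces) {
  if (inherits(traces, "deer_trace")) traces <- list(traces)
  if (inherits(traces, "deer_traceset")) traces <- unclass(traces)
  if (!is.list(traces) || length(traces) == 0 ||
      !all(vapply(traces, inherits, logical(1), "deer_trace")))
    stop("traces must be a deer_trace, deer_traceset, or list of deer_trace")
  traces
}

# second-difference penalty operator
.second_diff <- function(n) {
  L <- matrix(0, n - 2, n)
  for (i in seq_len(n - 2)) L[i, i:(i + 2)] <- c(1, -2, 1)
  L
}

# tail-based initial nuisance estimate for one trace
.init_nuisance <- function(tr, d) {
  n <- length(tr$t)
  tail_idx <- seq.int(max(2, floor(0.55 * n)), n)
  Vs <- pmax(tr$V, 1e-6)
  x <- tr$t[tail_idx]^(d / 3)
  fit <- stats::lm.fit(cbind(1, -x), log(Vs[tail_idx]))
  k <- max(0, fit$coefficients[2])
  lam <- 1 - exp(fit$coefficients[1]) / tr$V[1]
  lam <- min(max(lam, 0.05), 0.8)
  list(lambda = lam, k = k, V0 = tr$V[1])
}

# assemble normal equations for fixed nuisance parameters
.assemble <- function(prob, pars) {
  n_r <- length(prob$r)
  AtA <- matrix(0, n_r, n_r)
  Atb <- numeric(n_r)
  for (i in seq_along(prob$traces)) {
    tr <- prob$traces[[i]]
    p <- pars[[i]]
    B <- background_value(tr$t, p$k, prob$d)
    u <- p$V0 * p$lambda * B / prob$sigma_rel[i]
    Au <- prob$K[[i]] * u
    b <- (tr$V - p$V0 * (1 - p$lambda) * B) / prob$sigma_rel[i]
    AtA <- AtA + crossprod(Au)
    Atb <- Atb + drop(crossprod(Au, b))
  }
  list(AtA = AtA, Atb = Atb)
}

.make_problem <- function(traces, axis, d) {
  traces <- .as_traceset(traces)
  sigma <- vapply(traces, function(tr) {
    s <- tr$sigma %||% NA_real_
    if (!is.finite(s) || s <= 0) s <- estimate_noise(tr$V)
    max(s, 1e-4)  # floor keeps the weighting well-conditioned for clean traces
  }, numeric(1))
  K <- lapply(traces, function(tr) build_kernel(tr$t, axis))
  w <- .trapz_weights(axis)
  m <- sum(vapply(traces, function(tr) length(tr$t), numeric(1)))
  # weights are relative (sigma_ref / sigma_i) so the problem scale, and
  # hence the meaning of alpha, is independent of the absolute noise level;
  # the unit-integral row gets a fixed moderate weight relative to the data
  list(traces = traces, r = axis, d = d, sigma = sigma,
       sigma_rel = sigma / mean(sigma), K = K,
       w = w, wn = 10 * sqrt(m) / sum(w), L = .second_diff(length(axis)),
       m = m)
}

# inner regularised non-negative solve; returns density and passive set
.solve_P <- function(prob, nq, alpha) {
  n_r <- length(prob$r)
  AtA <- nq$AtA + prob$wn^2 * outer(prob$w, prob$w) +
    alpha^2 * crossprod(prob$L)
  Atb <- nq$Atb + prob$wn^2 * prob$w
  sol <- fnnls_cpp(AtA, Atb)
  list(P = drop(sol$x), passive = drop(sol$passive),
       converged = sol$converged, AtA_pen = AtA)
}

# weighted data residuals for current (P, pars)
.resid <- function(prob, pars, P) {
  lapply(seq_along(prob$traces), function(i) {
    tr <- prob$traces[[i]]
    p <- pars[[i]]
    B <- background_value(tr$t, p$k, prob$d)
    model <- p$V0 * ((1 - p$lambda) + p$lambda * drop(prob$K[[i]] %*% P)) * B
    (tr$V - model) / prob$sigma_rel[i]
  })
}

.rss <- function(prob, pars, P) sum(vapply(.resid(prob, pars, P),
                                           function(r) sum(r^2), numeric(1)))

# selection criteria on the weighted linear subproblem
.criterion_at <- function(prob, nq, pars, alpha, criterion, gamma) {
  sol <- .solve_P(prob, nq, alpha)
  rss <- .rss(prob, pars, sol$P)
  Fset <- sol$passive
  if (length(Fset) == 0) return(list(value = Inf, dof = 0, P = sol$P))
  M <- sol$AtA_pen[Fset, Fset, drop = FALSE]
  Minv <- tryCatch(chol2inv(chol(M)), error = function(e) NULL)
  if (is.null(Minv))
    stop("singular influence matrix at alpha = ", signif(alpha, 3),
         "; condition estimate ", signif(kappa(M), 3))
  Ad <- do.call(rbind, lapply(seq_along(prob$traces), function(i) {
    tr <- prob$traces[[i]]
    p <- pars[[i]]
    B <- background_value(tr$t, p$k, prob$d)
    (prob$K[[i]] * (p$V0 * p$lambda * B / prob$sigma_rel[i]))[, Fset, drop = FALSE]
  }))
  H_diag_part <- (Ad %*% Minv) * Ad
  trH <- sum(H_diag_part)
  m <- prob$m
  gcv <- m * rss / (m - min(trH, m - 1))^2
  val <- if (criterion == "gcv") gcv else {
    # strong-robust penalty after Lukas: grows as the regularised inverse
    # A_alpha^dagger inflates at small alpha; made dimensionless (and
    # invariant to the overall data scale) with the mean squared row norm
    G <- crossprod(Ad)                      # AtA of data rows on passive set
    mu <- sum((Minv %*% G) * Minv) * sum(diag(G)) / (m^2 * ncol(G))
    gcv * (gamma + (1 - gamma) * mu)
  }
  list(value = val, dof = trH, P = sol$P)
}

#' Select the Tikhonov regularisation parameter
#'
#' Scans a log-spaced grid of alpha values and returns the minimiser of the
#' generalised cross-validation criterion ("gcv") or its strong-robust
#' variant ("srgcv", GCV times the Lukas penalty `gamma + (1 - gamma) *
#' tr(Adag' Adag)/m` with tuning parameter gamma).  Ties break toward larger
#' alpha (stronger smoothing).
#'
#' @param traces trace(s) as for [deer_fit()].
#' @param axis distance axis.
#' @param criterion "srgcv" (default) or "gcv".
#' @param alpha_grid grid of alpha values (default 25 points spanning
#'   1e-4 to 1e2).
#' @param gamma robustness tuning parameter in (0, 1], default 0.8.
#' @param pars optional list of per-trace nuisance parameters
#'   (`lambda`, `k`, `V0`); estimated from the trace tails if omitted.
#' @param d background stretch dimensionality.
#' @return list with `alpha`, `grid`, `values` (criterion curve), `dof`.
#' @export
select_alpha <- function(traces, axis = distance_axis(),
                         criterion = c("srgcv", "gcv"),
                         alpha_grid = NULL, gamma = 0.8, pars = NULL, d = 3) {
  criterion <- match.arg(criterion)
  grid <- alpha_grid %||% 10^seq(-4, 2, length.out = 25)
  if (length(grid) < 20 || (log10(max(grid)) - log10(min(grid))) < 6)
    stop("alpha grid must have >= 20 points spanning >= 6 decades")
  prob <- .make_problem(traces, axis, d)
  if (is.null(pars)) pars <- lapply(prob$traces, .init_nuisance, d = d)
  nq <- .assemble(prob, pars)
  scan <- .scan_alpha(prob, nq, pars, grid, criterion, gamma)
  c(scan, list(criterion = criterion))
}

.scan_alpha <- function(prob, nq, pars, grid, criterion, gamma) {
  grid <- sort(grid)
  vals <- numeric(length(grid))
  dofs <- numeric(length(grid))
  for (j in seq_along(grid)) {
    cr <- .criterion_at(prob, nq, pars, grid[j], criterion, gamma)
    vals[j] <- cr$value
    dofs[j] <- cr$dof
  }
  best <- max(which(vals <= min(vals) + 1e-12))  # ties -> larger alpha
  list(alpha = grid[best], grid = grid, values = vals, dof = dofs)
}

# ---- main fitting function ----------------------------------------------

#' Fit a shared distance distribution to one or several dipolar traces
#'
#' Global non-negative Tikhonov inversion: one distance distribution P(r) is
#' recovered jointly from all traces, each trace carrying its own modulation
#' depth, background rate and scale.  The fit alternates a convex inner
#' solve for P (non-negative least squares with a second-difference
#' smoothness penalty and a unit-integral constraint) with bounded
#' per-trace nuisance refinement, weighting each trace by its inverse noise
#' variance.  The regularisation parameter is chosen by (strong robust)
#' generalised cross-validation.
#'
#' @param traces a `deer_trace`, `deer_traceset`, or list of traces (1-6).
#' @param axis distance axis, nm.
#' @param criterion alpha selection criterion, "srgcv" or "gcv".
#' @param alpha fixed regularisation parameter; overrides selection.
#' @param alpha_grid selection grid (see [select_alpha()]).
#' @param gamma strong-robust tuning parameter.
#' @param d background stretch dimensionality (fixed, not fitted).
#' @param max_rounds maximum alternation rounds.
#' @param rtol relative objective tolerance for convergence.
#' @return an object of class `deer_fit`: recovered `distribution` (a
#'   `ddist`), per-trace nuisance table `pars`, `alpha` and the selection
#'   `alpha_curve`, per-trace `residuals` and `fitted` values,
#'   trace-length `reliability` ranges, and `diagnostics` (convergence,
#'   flags such as "low modulation depth").
#' @seealso [fit_single()], [fit_global()], [jackknife_traces()]
#' @examples
#' gt <- make_ground_truth(
#'   data.frame(mean = 4, sd = 0.3, weight = 1), distance_axis(2, 6, 0.1))
#' tr <- simulate_trace(gt, trace_spec(t_max = 2, dt = 0.03, noise_sd = 0.002))
#' fit <- deer_fit(tr, distance_axis(2, 6, 0.1))
#' ddist_moments(fit$distribution)
#' @export
deer_fit <- function(traces, axis = distance_axis(),
                     criterion = c("srgcv", "gcv"), alpha = NULL,
                     alpha_grid = NULL, gamma = 0.8, d = 3,
                     max_rounds = 40, rtol = 1e-4) {
  criterion <- match.arg(criterion)
  cl <- match.call()
  prob <- .make_problem(traces, axis, d)
  grid <- alpha_grid %||% 10^seq(-4, 2, length.out = 25)
  pars <- lapply(prob$traces, .init_nuisance, d = d)

  refine <- function(pars, P) {
    for (i in seq_along(prob$traces)) {
      tr <- prob$traces[[i]]
      Fm <- drop(prob$K[[i]] %*% P)
      obj <- function(th) {
        lam <- th[1]; kk <- th[2]
        M <- ((1 - lam) + lam * Fm) * background_value(tr$t, kk, prob$d)
        V0 <- sum(tr$V * M) / sum(M * M)
        sum((tr$V - V0 * M)^2)
      }
      o <- optim(c(pars[[i]]$lambda, pars[[i]]$k), obj, method = "L-BFGS-B",
                 lower = c(1e-4, 0), upper = c(0.99, 5))
      lam <- o$par[1]; kk <- o$par[2]
      M <- ((1 - lam) + lam * Fm) * background_value(tr$t, kk, prob$d)
      pars[[i]] <- list(lambda = lam, k = kk,
                        V0 = sum(tr$V * M) / sum(M * M))
    }
    pars
  }

  # warm the nuisance estimate at a deliberately small alpha: with minimal
  # smoothing the distribution can absorb any shape, so the modulation
  # depths converge without the upward bias that an over-smoothed P induces
  # through the depth-width degeneracy; only then scan for alpha
  curve <- NULL
  fixed_alpha <- !is.null(alpha)
  if (!fixed_alpha) {
    for (it in 1:4) {
      nq <- .assemble(prob, pars)
      P <- .solve_P(prob, nq, 0.01)$P
      pars <- refine(pars, P)
    }
    nq <- .assemble(prob, pars)
    scan <- .scan_alpha(prob, nq, pars, grid, criterion, gamma)
    alpha <- scan$alpha
    curve <- data.frame(alpha = scan$grid, value = scan$values,
                        dof = scan$dof)
  }
  # alternate inner solve and nuisance refinement at the selected alpha;
  # after convergence re-scan alpha once (the selection depends weakly on
  # the nuisance estimate) and continue if it moved
  obj_prev <- Inf
  converged <- FALSE
  rounds <- 0L
  inner_ok <- TRUE
  rescanned <- fixed_alpha
  P <- NULL
  obj <- Inf
  for (it in seq_len(max_rounds)) {
    rounds <- it
    nq <- .assemble(prob, pars)
    sol <- .solve_P(prob, nq, alpha)
    inner_ok <- inner_ok && sol$converged
    P <- sol$P
    pars <- refine(pars, P)
    obj <- .rss(prob, pars, P) + alpha^2 * sum((prob$L %*% P)^2)
    if (is.finite(obj_prev) &&
        abs(obj_prev - obj) <= rtol * max(obj, 1e-12)) {
      if (!rescanned) {
        rescanned <- TRUE
        nq <- .assemble(prob, pars)
        scan <- .scan_alpha(prob, nq, pars, grid, criterion, gamma)
        curve <- data.frame(alpha = scan$grid, value = scan$values,
                            dof = scan$dof)
        if (abs(log(scan$alpha) - log(alpha)) > 1e-9) {
          alpha <- scan$alpha
          obj_prev <- Inf
          next
        }
      }
      converged <- TRUE
      break
    }
    obj_prev <- obj
  }
  dist <- distance_distribution(prob$r, P, normalize = TRUE)
  res <- .resid(prob, pars, P)
  fitted <- lapply(seq_along(prob$traces), function(i)
    prob$traces[[i]]$V - res[[i]] * prob$sigma_rel[i])
  res <- lapply(seq_along(res), function(i)
    res[[i]] * prob$sigma_rel[i] / prob$sigma[i])  # noise-scaled residuals
  flags <- character(0)
  lam_hat <- vapply(pars, `[[`, numeric(1), "lambda")
  if (any(lam_hat < 0.02)) flags <- c(flags, "low modulation depth")
  if (!converged || !inner_ok) flags <- c(flags, "not converged")
  partab <- data.frame(
    label = vapply(prob$traces, function(tr) tr$label %||% "", character(1)),
    t_max = vapply(prob$traces, function(tr) max(tr$t), numeric(1)),
    n = vapply(prob$traces, function(tr) length(tr$t), numeric(1)),
    lambda = lam_hat,
    k = vapply(pars, `[[`, numeric(1), "k"),
    d = d,
    V0 = vapply(pars, `[[`, numeric(1), "V0"),
    sigma = prob$sigma)
  structure(list(
    distribution = dist, pars = partab, alpha = alpha,
    criterion = criterion, alpha_curve = curve,
    residuals = res, fitted = fitted,
    traces = prob$traces,
    reliability = lapply(partab$t_max, reliability_ranges),
    diagnostics = list(converged = converged && inner_ok, rounds = rounds,
                       objective = obj_prev, flags = flags,
                       integral = ddist_integral(dist)),
    call = cl), class = "deer_fit")
}

#' @rdname deer_fit
#' @param trace a single `deer_trace`.
#' @param ... passed to [deer_fit()].
#' @export
fit_single <- function(trace, axis = distance_axis(), ...) {
  traces <- .as_traceset(trace)
  if (length(traces) != 1) stop("fit_single expects exactly one trace")
  deer_fit(traces, axis, ...)
}

#' @rdname deer_fit
#' @export
fit_global <- function(traces, axis = distance_axis(), ...) {
  deer_fit(traces, axis, ...)
}

# ---- methods -------------------------------------------------------------

#' @export
print.deer_fit <- function(x, ...) {
  mo <- ddist_moments(x$distribution)
  cat(sprintf(
    "Global regularised DEER fit: %d trace(s), alpha = %.3g (%s)\n",
    nrow(x$pars), x$alpha, x$criterion))
  cat(sprintf("  P(r): mean %.2f nm, sd %.2f nm on [%.2f, %.2f] nm\n",
              mo["mean"], mo["sd"], min(x$distribution$r),
              max(x$distribution$r)))
  print(x$pars, digits = 3, row.names = FALSE)
  if (length(x$diagnostics$flags))
    cat("  flags:", paste(x$diagnostics$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.deer_fit <- function(object, ...) {
  out <- list(fit = object, moments = ddist_moments(object$distribution),
              rss = sum(vapply(object$residuals, function(r) sum(r^2),
                               numeric(1))),
              reliability = object$reliability)
  class(out) <- "summary.deer_fit"
  out
}

#' @export
print.summary.deer_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  weighted RSS: %.4g\n", x$rss))
  rel <- x$reliability[[which.max(x$fit$pars$t_max)]]
  cat(sprintf("  reliability (longest trace): shape to %.1f nm, mean+width to %.1f nm, mean to %.1f nm\n",
              rel$r_shape, rel$r_mean_width, rel$r_mean))
  invisible(x)
}

#' @export
coef.deer_fit <- function(object, ...) {
  m <- as.matrix(object$pars[, c("lambda", "k", "V0")])
  rownames(m) <- object$pars$label
  m
}

#' @export
residuals.deer_fit <- function(object, weighted = FALSE, ...) {
  if (weighted) object$residuals
  else lapply(seq_along(object$residuals), function(i)
    object$residuals[[i]] * object$pars$sigma[i])
}

#' @export
fitted.deer_fit <- function(object, ...) object$fitted

#' Predict model traces from a fitted inversion
#' @param object a `deer_fit`.
#' @param times new time axis (us); defaults to the fitted times.
#' @param trace trace index whose nuisance parameters to use.
#' @param ... unused.
#' @export
predict.deer_fit <- function(object, times = NULL, trace = 1, ...) {
  p <- object$pars[trace, ]
  t <- times %||% object$traces[[trace]]$t
  dipolar_signal(object$distribution, t, p$lambda, p$k, p$d, p$V0)
}

#' @export
plot.deer_fit <- function(x, which = c("traces", "distribution"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  op <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(op))
  if ("traces" %in% which) {
    off <- 0
    graphics::plot(NA, xlim = c(0, max(x$pars$t_max)),
                   ylim = c(0.3 - 0.15 * nrow(x$pars), 1.05),
                   xlab = "t (us)", ylab = "V(t) + offset")
    for (i in seq_len(nrow(x$pars))) {
      graphics::lines(x$traces[[i]]$t, x$traces[[i]]$V - off, col = "grey40")
      graphics::lines(x$traces[[i]]$t, x$fitted[[i]] - off, col = "blue")
      off <- off + 0.15
    }
  }
  if ("distribution" %in% which) {
    plot(x$distribution, main = sprintf("alpha = %.3g", x$alpha))
    rel <- x$reliability[[which.max(x$pars$t_max)]]
    graphics::abline(v = c(rel$r_shape, rel$r_mean_width, rel$r_mean),
                     col = c("green3", "gold", "orange"), lty = 2)
  }
  invisible(x)
}

#' Trace-length reliability ranges for a distance distribution
#'
#' Distances below `r_shape` have a reliable distribution shape, below
#' `r_mean_width` a reliable mean and width, below `r_mean` a reliable mean
#' only; beyond that no quantification is possible.  The ranges scale with
#' the cube root of the dipolar evolution window: r_X = c_X (t_max / 2)^(1/3)
#' with defaults c = 5.0 / 6.0 / 7.0 nm, the colour-bar convention of
#' standard DEER analysis tools.
#'
#' @param t_max dipolar evolution window, us.
#' @param constants named vector with `shape`, `mean_width`, `mean` (nm at
#'   t_max = 2 us).
#' @return a `reliability_ranges` list.
#' @export
reliability_ranges <- function(t_max,
                               constants = c(shape = 5, mean_width = 6,
                                             mean = 7)) {
  if (t_max <= 0) stop("t_max must be positive")
  s <- (t_max / 2)^(1 / 3)
  structure(list(r_shape = constants[["shape"]] * s,
                 r_mean_width = constants[["mean_width"]] * s,
                 r_mean = constants[["mean"]] * s,
                 t_max = t_max), class = "reliability_ranges")
}

#' @export
print.reliability_ranges <- function(x, ...) {
  cat(sprintf("t_max %.2f us: shape <= %.2f nm, mean+width <= %.2f nm, mean <= %.2f nm\n",
              x$t_max, x$r_shape, x$r_mean_width, x$r_mean))
  invisible(x)
}

#' Leave-one-trace-out robustness analysis
#'
#' Repeats the global fit omitting one trace at a time and summarises the
#' dispersion of the recovered distributions; systematic omission of single
#' traces should leave the distribution essentially unchanged when the data
#' are self-consistent.
#'
#' @param traces a trace set with >= 3 traces.
#' @param axis distance axis.
#' @param alpha regularisation parameter held fixed across the leave-one-out
#'   fits so the jackknife isolates the influence of the data from that of
#'   the processing; defaults to the value selected on the full trace set.
#' @param ... passed to [deer_fit()].
#' @return list with `fits` (one per omitted trace), `l1` (pairwise L1
#'   distance matrix between recovered distributions), `max_l1` and the
#'   `alpha` used.
#' @export
jackknife_traces <- function(traces, axis = distance_axis(), alpha = NULL,
                             ...) {
  traces <- .as_traceset(traces)
  n <- length(traces)
  if (n < 3) stop("jackknife needs at least 3 traces")
  if (is.null(alpha)) alpha <- deer_fit(traces, axis, ...)$alpha
  fits <- lapply(seq_len(n), function(i)
    deer_fit(traces[-i], axis, alpha = alpha, ...))
  l1 <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    l1[i, j] <- l1[j, i] <- ddist_l1(fits[[i]]$distribution,
                                     fits[[j]]$distribution)
  }
  list(fits = fits, l1 = l1, max_l1 = max(l1), alpha = alpha)
}
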