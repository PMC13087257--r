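#' Nernst equilibrium potential
#'
#' E = (R T)/(z F) ln(c_out / c_in) in mV.  For potassium in a 10-fold
#' inward gradient (c_out/c_in = 0.1) at 298.15 K this gives -59.2 mV,
#' commonly quoted as -59 mV.
#'
#' @param temperature temperature, K (> 0).
#' @param z ion valence (non-zero).
#' @param ratio_out_over_in concentration ratio c_out / c_in (> 0).
#' @return equilibrium potential, mV.
#' @examples
#' nernst_potential(298.15, 1, 0.1)   # about -59.2
#' @export
nernst_potential <- function(temperature = 298.15, z = 1,
                             ratio_out_over_in) {
  R <- 8.314462618   # J/(mol K)
  Faraday <- 96485.33212  # C/mol
  if (temperature <= 0) stop("temperature must be positive")
  if (z == 0) stop("valence must be non-zero")
  if (any(ratio_out_over_in <= 0)) stop("concentration ratio must be positive")
  1000 * R * temperature / (z * Faraday) * log(ratio_out_over_in)
}

#' Fold activation over baseline, per patch
#'
#' Per-patch fold change stimulated/baseline with mean and SEM (SD/sqrt(n))
#' across patches, the convention for reporting e.g. tension- or
#' lipid-induced activation of channel currents.
#'
#' @param baseline,stimulated equal-length per-patch current vectors;
#'   baselines must be non-zero.
#' @return object of class `fold_change`: `folds`, `mean`, `sem`, `n`,
#'   `sem_defined` (FALSE for a single patch).
#' @examples
#' fold_activation(c(10, 10, 10, 10), c(15, 16, 17, 16))
#' @export
fold_activation <- function(baseline, stimulated) {
  if (length(baseline) != length(stimulated))
    stop("baseline and stimulated must be paired, equal-length vectors")
  if (length(baseline) < 1) stop("need at least one patch")
  zero <- which(baseline == 0)
  if (length(zero))
    stop("zero baseline current in patch ", paste(zero, collapse = ", "))
  folds <- stimulated / baseline
  n <- length(folds)
  structure(list(folds = folds, mean = mean(folds),
                 sem = if (n > 1) stats::sd(folds) / sqrt(n) else NA_real_,
                 n = n, sem_defined = n > 1), class = "fold_change")
}

#' @export
print.fold_change <- function(x, ...) {
  if (x$sem_defined)
    cat(sprintf("%.2f +/- %.2f -fold (mean +/- SEM, n = %d patches)\n",
                x$mean, x$sem, x$n))
  else
    cat(sprintf("%.2f -fold (single patch; SEM undefined)\n", x$mean))
  invisible(x)
}
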