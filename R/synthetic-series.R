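#' Specification of a synthetic interaction-energy series
#'
#' Describes the statistical structure of a gas-phase interaction-energy trace:
#' a stationary mean with Gaussian fluctuations, optional AR(1) autocorrelation,
#' optional regime changes (segments with their own mean/sigma) and optional
#' symmetric two-sided outlier contamination. These are exactly the features
#' the interaction-entropy workflow has to cope with: window selection keys on
#' regime changes, the 3-sigma filter on outliers, convergence on sigma and
#' autocorrelation.
#'
#' @param n_points number of samples.
#' @param dt sampling interval, ps (default 1, one snapshot per ps).
#' @param mean stationary mean, kcal/mol.
#' @param sigma fluctuation SD, kcal/mol (>= 0).
#' @param autocorrelation_time AR(1) correlation time, ps; 0 = white noise.
#' @param regime_changes optional list of `list(start_index, mean, sigma)`
#'   entries; each segment runs to the next start (or the end).
#' @param outlier_fraction proportion of points replaced by outliers, in
#'   `[0, 0.5)`.
#' @param outlier_scale outlier magnitude threshold in multiples of the local
#'   sigma (injected points are at least this far from the local mean).
#' @param seed RNG seed; output is a pure function of spec + seed.
#' @return A list of class `SeriesSpec`.
#' @export
series_spec <- function(n_points, dt = 1, mean = 0, sigma = 1,
                        autocorrelation_time = 0, regime_changes = NULL,
                        outlier_fraction = 0, outlier_scale = 8, seed = 1) {
  if (n_points < 2) stop("n_points must be >= 2")
  if (sigma < 0) stop("sigma must be >= 0")
  if (dt <= 0) stop("dt must be > 0")
  if (outlier_fraction < 0 || outlier_fraction >= 0.5)
    stop("outlier_fraction must be in [0, 0.5)")
  if (!is.null(regime_changes)) {
    starts <- vapply(regime_changes, `[[`, 1, "start_index")
    if (any(starts < 1 | starts > n_points) || any(diff(starts) <= 0))
      stop("regime start indices must be increasing and within the series")
  }
  structure(list(n_points = as.integer(n_points), dt = dt, mean = mean,
                 sigma = sigma, autocorrelation_time = autocorrelation_time,
                 regime_changes = regime_changes,
                 outlier_fraction = outlier_fraction,
                 outlier_scale = outlier_scale, seed = seed),
            class = "SeriesSpec")
}

#' Generate a synthetic interaction-energy series
#'
#' Draws a unit-variance noise process (white, or AR(1) with
#' `phi = exp(-dt / autocorrelation_time)` started from its stationary
#' distribution), scales and shifts it segment-wise according to the regime
#' schedule, then replaces a seeded random subset of points with symmetric
#' outliers at `>= outlier_scale * sigma_local` from the local mean.
#' Deterministic under the spec seed.
#'
#' @param spec a [series_spec()].
#' @return An [energy_series()] with times `dt * (0, 1, ..., n-1)`.
#' @export
gen_energy_series <- function(spec) {
  stopifnot(inherits(spec, "SeriesSpec"))
  n <- spec$n_points
  with_seed(spec$seed, {
    if (spec$autocorrelation_time > 0) {
      phi <- exp(-spec$dt / spec$autocorrelation_time)
      innov <- stats::rnorm(n)
      z <- numeric(n)
      z[1] <- innov[1]
      s <- sqrt(1 - phi^2)
      for (i in 2:n) z[i] <- phi * z[i - 1] + s * innov[i]
    } else {
      z <- stats::rnorm(n)
    }
    seg_mean <- rep(spec$mean, n)
    seg_sd <- rep(spec$sigma, n)
    if (!is.null(spec$regime_changes)) {
      regs <- spec$regime_changes
      starts <- vapply(regs, `[[`, 1, "start_index")
      ends <- c(starts[-1] - 1, n)
      for (k in seq_along(regs)) {
        i <- starts[k]:ends[k]
        seg_mean[i] <- regs[[k]]$mean
        seg_sd[i] <- regs[[k]]$sigma
      }
    }
    x <- seg_mean + seg_sd * z
    n_out <- round(spec$outlier_fraction * n)
    if (n_out > 0) {
      idx <- sample.int(n, n_out)
      sgn <- sample(c(-1, 1), n_out, replace = TRUE)
      mag <- spec$outlier_scale + stats::rexp(n_out)
      x[idx] <- seg_mean[idx] + sgn * mag * seg_sd[idx]
    }
    energy_series(spec$dt * (seq_len(n) - 1), x, label = "synthetic")
  })
}
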