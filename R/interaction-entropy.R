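# Interaction-entropy estimation: -TdS = kT ln < exp(beta dE_int) > over the
# mean-centered gas-phase interaction energy, after selecting the
# minimum-fluctuation time window and applying a single-pass 3-sigma energy
# noise filter.

#' Sliding-window fluctuation (energy RMSF) scan
#'
#' For every admissible start, the root-mean-square fluctuation of the
#' interaction energy over `[t, t + window_length)`:
#' `RMSF = sqrt(mean((E - mean(E))^2))` (population form). Computed in O(n)
#' via cumulative sums.
#'
#' @param series an [energy_series()].
#' @param window_length window length, ps.
#' @return List of class `WindowScan` with `starts` (start times),
#'   `start_idx`, `rmsf` (kcal/mol), `n_per_window` and `window_length`.
#' @export
scan_windows <- function(series, window_length) {
  dt <- series$times[2] - series$times[1]
  w <- round(window_length / dt)
  n <- length(series$values)
  if (w < 2) stop("window shorter than two samples")
  if (w > n) stop("window longer than the series")
  x <- series$values
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  i <- seq_len(n - w + 1L)
  m <- (cs[i + w] - cs[i]) / w
  v <- (cs2[i + w] - cs2[i]) / w - m^2
  structure(list(starts = series$times[i], start_idx = i,
                 rmsf = sqrt(pmax(v, 0)), n_per_window = w,
                 window_length = window_length),
            class = "WindowScan")
}

#' Select the minimum-fluctuation window
#'
#' Argmin of the RMSF scan; ties broken by earliest start.
#'
#' @param scan a [scan_windows()] result.
#' @return List with `start_time`, `end_time`, `start_idx`, `end_idx`,
#'   `rmsf`.
#' @export
select_window <- function(scan) {
  if (!length(scan$rmsf)) stop("empty window scan")
  k <- which.min(scan$rmsf)
  i <- scan$start_idx[k]
  list(start_time = scan$starts[k],
       end_time = scan$starts[k] + scan$window_length,
       start_idx = i, end_idx = i + scan$n_per_window - 1L,
       rmsf = scan$rmsf[k])
}

#' Discard energy-noise outliers (single pass)
#'
#' Computes the mean and SD of the input window and drops points more than
#' `k_sigma` standard deviations from the mean (two-sided, default 3). A
#' constant series (SD = 0) keeps all points. Discarding everything is an
#' error.
#'
#' @param series an [energy_series()].
#' @param k_sigma positive multiple of the SD.
#' @return List with `series` (kept points) and `n_discarded`.
#' @export
filter_outliers <- function(series, k_sigma = 3) {
  if (k_sigma <= 0) stop("k_sigma must be > 0")
  x <- series$values
  s <- stats::sd(x)
  if (s == 0) return(list(series = series, n_discarded = 0L))
  keep <- abs(x - mean(x)) <= k_sigma * s
  if (!any(keep)) stop("all points discarded by the outlier filter")
  list(series = energy_series(series$times[keep], x[keep], series$label),
       n_discarded = sum(!keep))
}

#' Interaction-entropy estimate of -TdS
#'
#' Centers the series by its own mean (`dE_int = E_int - <E_int>`), then
#' returns `kT ln < exp(dE_int / kT) >`, evaluated with a log-sum-exp guard.
#' By Jensen's inequality the estimate is >= 0; tiny negative round-off is
#' clamped to 0. The convergence trace gives the running estimate on growing
#' prefixes (centering fixed at the full-window mean).
#'
#' @param series an [energy_series()] (>= 100 points).
#' @param temperature K.
#' @param n_discarded bookkeeping from a preceding [filter_outliers()] call.
#' @param trace_points number of prefix checkpoints kept in the trace.
#' @return List of class `IeResult` with `minus_t_delta_s` (kcal/mol),
#'   `n_used`, `n_discarded`, `window` (time range, ps) and
#'   `convergence_trace` (data.frame time / estimate).
#' @export
ie_entropy <- function(series, temperature = 300, n_discarded = 0L,
                       trace_points = 200L) {
  x <- series$values
  n <- length(x)
  if (n < 100L) stop("need at least 100 points after filtering")
  kT <- kt(temperature)
  d <- x - mean(x)
  if (abs(mean(d)) > 1e-9 * max(stats::sd(d), 1e-30))
    stop("internal error: centering failed")
  b <- d / kT
  m <- max(b)
  # prefix log-sum-exp: exponents shifted by the global max stay <= 0
  lse <- m + log(cumsum(exp(b - m)))
  est <- kT * (lse - log(seq_len(n)))
  idx <- unique(round(seq(1, n, length.out = min(trace_points, n))))
  structure(list(minus_t_delta_s = max(est[n], 0),
                 n_used = n, n_discarded = as.integer(n_discarded),
                 window = c(series$times[1], series$times[n]),
                 convergence_trace = data.frame(time = series$times[idx],
                                                estimate = pmax(est[idx], 0))),
            class = "IeResult")
}

#' @export
print.IeResult <- function(x, ...) {
  cat(sprintf("IE: -TdS = %.4f kcal/mol (%d points used, %d discarded, window [%g, %g] ps)\n",
              x$minus_t_delta_s, x$n_used, x$n_discarded,
              x$window[1], x$window[2]))
  invisible(x)
}

#' Full interaction-entropy workflow on a raw series
#'
#' Window selection first (minimum energy RMSF over `window_length`), then the
#' single-pass `k_sigma` filter on the selected window, then [ie_entropy()].
#'
#' @param series raw [energy_series()].
#' @param window_length analysis window, ps (default 10 ns).
#' @param temperature K.
#' @param k_sigma outlier threshold in SD multiples.
#' @return An `IeResult` (window field reports the selected window).
#' @export
ie_analysis <- function(series, window_length = 10000, temperature = 300,
                        k_sigma = 3) {
  sel <- select_window(scan_windows(series, window_length))
  win <- energy_series(series$times[sel$start_idx:sel$end_idx],
                       series$values[sel$start_idx:sel$end_idx],
                       series$label)
  flt <- filter_outliers(win, k_sigma = k_sigma)
  ie_entropy(flt$series, temperature = temperature,
             n_discarded = flt$n_discarded)
}

#' Combine enthalpy and interaction entropy into a binding free energy
#'
#' `dG = dH + (-TdS)`. Accepts plain numbers or the package's summary
#' objects.
#'
#' @param dh mean enthalpy (kcal/mol) or an `EnthalpySummary`.
#' @param ie `-TdS` (kcal/mol) or an `IeResult`.
#' @return List with `dg`, `dh`, `minus_t_delta_s` (kcal/mol).
#' @export
binding_free_energy <- function(dh, ie) {
  dh_val <- if (inherits(dh, "EnthalpySummary")) dh$mean_dh else dh
  ie_val <- if (inherits(ie, "IeResult")) ie$minus_t_delta_s else ie
  list(dg = dh_val + ie_val, dh = dh_val, minus_t_delta_s = ie_val)
}

#' Average per-trajectory free energies and form a mutant-wild ddG
#'
#' Unweighted means across independent trajectories for the wild-type and
#' mutant systems; `ddg = mean(mutant) - mean(wild)`. Values are returned
#' unrounded; `round(x, 1)` matches the conventional 0.1 kcal/mol reporting
#' precision.
#'
#' @param wild,mutant numeric vectors of per-trajectory dG values, kcal/mol.
#' @return List with `wild_avg`, `mutant_avg`, `ddg` (NA when `mutant` is
#'   missing).
#' @export
average_and_ddg <- function(wild, mutant = NULL) {
  if (!length(wild)) stop("need at least one trajectory")
  wa <- mean(wild)
  if (is.null(mutant)) return(list(wild_avg = wa, mutant_avg = NA_real_,
                                   ddg = NA_real_))
  if (!length(mutant)) stop("need at least one mutant trajectory")
  ma <- mean(mutant)
  list(wild_avg = wa, mutant_avg = ma, ddg = ma - wa)
}

#' Block-bootstrap SD of the interaction-entropy estimate
#'
#' IE is a nonlinear functional of the series, so the usual SEM does not
#' apply; this resamples contiguous blocks (default 50) with replacement and
#' returns the SD of the re-estimates. Deterministic under `seed`.
#'
#' @param series filtered [energy_series()].
#' @param temperature K.
#' @param n_blocks number of blocks.
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed.
#' @return SD of `-TdS`, kcal/mol.
#' @export
ie_bootstrap_sd <- function(series, temperature = 300, n_blocks = 50,
                            n_boot = 100, seed = 1) {
  x <- series$values
  n <- length(x)
  bl <- floor(n / n_blocks)
  if (bl < 2) stop("series too short for the requested block count")
  blocks <- lapply(seq_len(n_blocks), function(b) x[((b - 1) * bl + 1):(b * bl)])
  kT <- kt(temperature)
  with_seed(seed, {
    ests <- vapply(seq_len(n_boot), function(i) {
      xb <- unlist(blocks[sample.int(n_blocks, replace = TRUE)])
      kT * log_mean_exp((xb - mean(xb)) / kT)
    }, numeric(1))
    stats::sd(ests)
  })
}
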