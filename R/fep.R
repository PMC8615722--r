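#' Free-energy-perturbation dataset
#'
#' Per lambda-window samples of the mixed potential `V_lambda` and the
#' perturbed-target potential `V_(lambda+dlambda)` evaluated on the same
#' configurations, with the lambda schedule and temperature. With K schedule
#' points there are K-1 forward windows, sampled at the lower lambda of each.
#'
#' @param lambdas strictly increasing schedule in `[0, 1]`, starting 0 and
#'   ending 1.
#' @param windows list of length `length(lambdas) - 1`; each element a
#'   data.frame with numeric columns `v_lambda` and `v_lambda_next`
#'   (kcal/mol), all with the same number of rows.
#' @param temperature K.
#' @return A list of class `FepDataset`.
#' @export
fep_dataset <- function(lambdas, windows, temperature = 300) {
  if (length(lambdas) < 2L || any(diff(lambdas) <= 0) ||
      abs(lambdas[1]) > 1e-12 || abs(lambdas[length(lambdas)] - 1) > 1e-12)
    stop("lambdas must increase strictly from 0 to 1")
  if (length(windows) != length(lambdas) - 1L)
    stopf("expected %d windows for %d lambdas, got %d",
          length(lambdas) - 1L, length(lambdas), length(windows))
  ns <- vapply(windows, nrow, 1L)
  if (length(unique(ns)) != 1L) stop("all windows must have equal sample counts")
  for (w in windows)
    if (!all(c("v_lambda", "v_lambda_next") %in% names(w)))
      stop("each window needs columns v_lambda and v_lambda_next")
  structure(list(lambdas = lambdas, windows = windows,
                 temperature = temperature, n_per_window = ns[1]),
            class = "FepDataset")
}

#' Exact Boltzmann samples for a harmonic mutation toy
#'
#' One-dimensional harmonic end states `V_wt = k_wt x^2 / 2` and
#' `V_mut = k_mut x^2 / 2` linearly mixed, `V_lambda = (1-lambda) V_wt +
#' lambda V_mut`, which is again harmonic with
#' `k_lambda = (1-lambda) k_wt + lambda k_mut`. Each window draws exact
#' Boltzmann samples `x ~ N(0, kT / k_lambda)` — no MD needed — and records
#' `V_lambda(x)` and `V_(lambda+dlambda)(x)`. The analytic total is
#' `(kT/2) ln(k_mut/k_wt)`, making the estimator testable to closed form.
#'
#' @param k_wt,k_mut force constants, kcal/(mol A^2), > 0.
#' @param lambdas schedule (default 11 equally spaced points).
#' @param n_per_window samples per window.
#' @param temperature K.
#' @param seed RNG seed.
#' @return A [fep_dataset()].
#' @export
gen_fep_samples <- function(k_wt, k_mut, lambdas = seq(0, 1, by = 0.1),
                            n_per_window = 1000, temperature = 300, seed = 1) {
  if (k_wt <= 0 || k_mut <= 0) stop("force constants must be > 0")
  kT <- kt(temperature)
  with_seed(seed, {
    windows <- lapply(seq_len(length(lambdas) - 1L), function(i) {
      kl <- (1 - lambdas[i]) * k_wt + lambdas[i] * k_mut
      kn <- (1 - lambdas[i + 1]) * k_wt + lambdas[i + 1] * k_mut
      x <- stats::rnorm(n_per_window, sd = sqrt(kT / kl))
      data.frame(v_lambda = 0.5 * kl * x^2, v_lambda_next = 0.5 * kn * x^2)
    })
    fep_dataset(lambdas, windows, temperature)
  })
}

#' Single-window FEP free energy
#'
#' The exponential-averaging (Zwanzig) estimator
#' `dG_lambda = -kT ln < exp(-(V_(lambda+dlambda) - V_lambda)/kT) >_lambda`,
#' evaluated with a log-sum-exp guard.
#'
#' @param v_lambda,v_lambda_next sampled potentials, kcal/mol (>= 10 samples).
#' @param temperature K.
#' @return dG for the window, kcal/mol.
#' @export
window_dg <- function(v_lambda, v_lambda_next, temperature = 300) {
  if (length(v_lambda) != length(v_lambda_next))
    stop("sample vectors must have equal length")
  if (length(v_lambda) < 10L) stop("need at least 10 samples per window")
  du <- v_lambda_next - v_lambda
  if (!all(is.finite(du))) stop("non-finite perturbation energies")
  kT <- kt(temperature)
  -kT * log_mean_exp(-du / kT)
}

#' Total relative free energy over the lambda schedule
#'
#' Sums [window_dg()] over all forward windows of a [fep_dataset()].
#'
#' @param dataset a `FepDataset`.
#' @return A list of class `FepResult` with `lambdas`, `per_window` (dG per
#'   window, kcal/mol), `per_window_sd` (sample SD of the perturbation
#'   energies) and `total` (kcal/mol).
#' @export
total_ddg <- function(dataset) {
  stopifnot(inherits(dataset, "FepDataset"))
  per <- vapply(dataset$windows, function(w)
    window_dg(w$v_lambda, w$v_lambda_next, dataset$temperature), numeric(1))
  sds <- vapply(dataset$windows, function(w)
    stats::sd(w$v_lambda_next - w$v_lambda), numeric(1))
  structure(list(lambdas = dataset$lambdas, per_window = per,
                 per_window_sd = sds, total = sum(per)),
            class = "FepResult")
}

#' @export
print.FepResult <- function(x, ...) {
  cat(sprintf("FEP: %d windows, total ddG = %.4f kcal/mol\n",
              length(x$per_window), x$total))
  invisible(x)
}

#' Softcore-mixed pair energy between two end states
#'
#' For a single atom pair with wild-type and mutant parameters, returns the
#' lambda-mixed interaction energy at separation `r`. When the LJ parameters
#' differ between end states the Beutler softcore form is used for the LJ
#' part (removes the r -> 0 singularity at interior lambda) while charges are
#' scaled linearly; when all parameters agree the plain linear mix
#' `(1-lambda) V_wt + lambda V_mut` applies.
#'
#' @param wt,mut pair parameters: lists with `eps` (kcal/mol, combined),
#'   `rmin` (A, combined rmin_i + rmin_j) and `qq` (product of charges, e^2).
#' @param lambda coupling parameter in `[0, 1]`.
#' @param r separation, A (>= 0).
#' @param alpha_sc softcore alpha (default 0.5).
#' @return Pair energy, kcal/mol.
#' @export
softcore_pair <- function(wt, mut, lambda, r, alpha_sc = 0.5) {
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  if (r < 0) stop("r must be >= 0")
  lj_plain <- function(p, r) {
    if (p$eps == 0) return(0)
    if (r == 0) stop("LJ singularity at r = 0 without softcore")
    p$eps * ((p$rmin / r)^12 - 2 * (p$rmin / r)^6)
  }
  # Beutler softcore in sigma^6 form; reduces to plain LJ when lam_off = 0
  lj_soft <- function(p, r, lam_off) {
    if (p$eps == 0) return(0)
    sig6 <- (p$rmin^6) / 2            # rmin = 2^(1/6) sigma
    den <- alpha_sc * lam_off * sig6 + r^6
    4 * p$eps * (sig6^2 / den^2 - sig6 / den)
  }
  coul <- function(qq, r) {
    if (qq == 0) return(0)
    if (r == 0) stop("Coulomb singularity at r = 0")
    KE * qq / r
  }
  differ <- !(isTRUE(all.equal(wt$eps, mut$eps)) &&
                isTRUE(all.equal(wt$rmin, mut$rmin)))
  qq_mix <- (1 - lambda) * wt$qq + lambda * mut$qq
  e_coul <- if (qq_mix == 0) 0 else coul(qq_mix, r)
  if (!differ) {
    e_lj <- (1 - lambda) * lj_plain(wt, r) + lambda * lj_plain(mut, r)
  } else {
    e_wt <- if (lambda == 0) lj_plain(wt, r) else lj_soft(wt, r, lambda)
    e_mut <- if (lambda == 1) lj_plain(mut, r) else lj_soft(mut, r, 1 - lambda)
    e_lj <- (1 - lambda) * e_wt + lambda * e_mut
  }
  e_lj + e_coul
}

#' Write / read a FEP dataset as one CSV per window
#'
#' `write_fep_dataset()` writes `window_01.csv`, ... plus `schedule.csv`
#' (lambda, temperature); `read_fep_dataset()` is its inverse.
#'
#' @param dataset a `FepDataset`.
#' @param dir directory.
#' @return The directory (write) or a `FepDataset` (read).
#' @export
write_fep_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(c("lambda,temperature",
               sprintf("%.17g,%.17g", dataset$lambdas,
                       rep(dataset$temperature, length(dataset$lambdas)))),
             file.path(dir, "schedule.csv"))
  for (i in seq_along(dataset$windows)) {
    w <- dataset$windows[[i]]
    writeLines(c("v_lambda,v_lambda_next",
                 sprintf("%.17g,%.17g", w$v_lambda, w$v_lambda_next)),
               file.path(dir, sprintf("window_%02d.csv", i)))
  }
  invisible(dir)
}

#' @rdname write_fep_dataset
#' @export
read_fep_dataset <- function(dir) {
  sched <- utils::read.csv(file.path(dir, "schedule.csv"))
  files <- sort(list.files(dir, pattern = "^window_\\d+\\.csv$",
                           full.names = TRUE))
  windows <- lapply(files, utils::read.csv)
  fep_dataset(sched$lambda, windows, temperature = sched$temperature[1])
}
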