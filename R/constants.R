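#' Physical constants used throughout the package
#'
#' `KB` is the Boltzmann constant in kcal/(mol K); `KE` is the Coulomb
#' electrostatic constant in kcal A/(mol e^2). All energies in the package are
#' kcal/mol, all lengths Angstrom, all temperatures Kelvin.
#'
#' @format Named numeric constants.
#' @name constants
NULL

#' @rdname constants
#' @export
KB <- 0.0019872041

#' @rdname constants
#' @export
KE <- 332.0637

# kT in kcal/mol at temperature T (K)
kt <- function(temperature) KB * temperature

# Numerically safe log-mean-exp: log( mean(exp(x)) )
log_mean_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) stop("non-finite values in exponential average")
  m + log(mean(exp(x - m)))
}

# Run code with a temporary RNG state seeded at `seed`; restores global state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
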