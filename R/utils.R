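## Internal helpers: physical constants and RNG discipline.

## Boltzmann constant in pN nm / K.
.kB <- 0.0138065

#' Thermal energy at a given temperature
#'
#' Returns \eqn{k_B T} in pN nm (0.0138065 pN nm/K times the absolute
#' temperature), the energy scale of all entropic-elasticity and
#' barrier-crossing formulas in this package. At 298 K this is 4.114 pN nm.
#'
#' @param temperature Absolute temperature in kelvin (> 0).
#' @return Thermal energy in pN nm.
#' @examples
#' thermalEnergy(298)  # 4.114 pN nm
#' @export
thermalEnergy <- function(temperature) {
  if (!is.numeric(temperature) || any(temperature <= 0))
    stop("temperature must be positive (kelvin)")
  .kB * temperature
}

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG state. All stochastic operations in the package funnel through this,
## so there is no hidden global RNG dependence.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv()),
        add = TRUE
      )
    }
    set.seed(as.integer(seed))
  }
  expr
}

## Deterministic stream of per-item seeds from a master seed, kept inside
## 32-bit integer range. Linear-congruential style scramble so neighbouring
## masters do not share streams.
deriveSeeds <- function(masterSeed, n) {
  m <- 2147483647
  s <- (as.numeric(masterSeed) %% m)
  vapply(seq_len(n), function(i) {
    as.integer((s * 48271 + i * 1664525 + 1013904223) %% m)
  }, integer(1))
}

## stopifnot-style scalar checks with readable messages
.assertScalar <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name))
  if (strict_lower && x <= lower)
    stop(sprintf("'%s' must be > %g", name, lower))
  if (!strict_lower && x < lower)
    stop(sprintf("'%s' must be >= %g", name, lower))
  if (x > upper)
    stop(sprintf("'%s' must be <= %g", name, upper))
  invisible(TRUE)
}
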