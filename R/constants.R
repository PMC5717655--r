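#' Model constants for huddling development
#'
#' Bundles the calibrated constants of the developmental huddling model.
#' Defaults are the published calibration for laboratory mice; any subset can
#' be overridden for sensitivity analyses.
#'
#' @param k Time constant of brown-adipose-tissue (BAT) depletion, in postnatal
#'   days; doubles as the energy scale of the metabolic-rate curve
#'   (cal g^-1 h^-1) and the asymptotic muscle mass (g).
#' @param c Asymptotic non-muscle mass, grams.
#' @param c1 Warm-preference coefficient: degrees C of preferred-temperature
#'   elevation per unit BAT fraction.
#' @param c2 Cool-preference coefficient: degrees C per unit of
#'   (metabolic rate x non-muscle mass).
#' @param Tp Target adult body temperature, degrees C.
#' @param beta Dimensionless scaling of the thermal huddling drive.
#' @param gamma Delta-rule learning rate, dimensionless, in `[0, 1)`; 0
#'   freezes the associations (useful for control-equivalence checks).
#' @param n Litter size (number of pups), at least 2.
#'
#' @return An object of class `huddle_constants`: a named list with the eight
#'   fields above.
#' @examples
#' huddle_constants()
#' huddle_constants(n = 12, gamma = 0.002)
#' @export
huddle_constants <- function(k = 8.31, c = 19, c1 = 3, c2 = 0.025,
                             Tp = 36, beta = 0.2, gamma = 0.001, n = 7L) {
  stopifnot(
    "k must be a single positive number" = is.numeric(k) && length(k) == 1 && is.finite(k) && k > 0,
    "c must be a single non-negative number" = is.numeric(c) && length(c) == 1 && is.finite(c) && c >= 0,
    "c1 must be a single non-negative number" = is.numeric(c1) && length(c1) == 1 && is.finite(c1) && c1 >= 0,
    "c2 must be a single non-negative number" = is.numeric(c2) && length(c2) == 1 && is.finite(c2) && c2 >= 0,
    "Tp must be a single finite number" = is.numeric(Tp) && length(Tp) == 1 && is.finite(Tp),
    "beta must be a single positive number" = is.numeric(beta) && length(beta) == 1 && is.finite(beta) && beta > 0,
    "gamma must lie in [0, 1)" = is.numeric(gamma) && length(gamma) == 1 && gamma >= 0 && gamma < 1,
    "n must be a whole number >= 2" = is.numeric(n) && length(n) == 1 && n >= 2 && n == as.integer(n)
  )
  structure(
    list(k = k, c = c, c1 = c1, c2 = c2, Tp = Tp,
         beta = beta, gamma = gamma, n = as.integer(n)),
    class = "huddle_constants"
  )
}

#' @export
print.huddle_constants <- function(x, ...) {
  cat("<huddle_constants>\n")
  cat(sprintf("  k  = %g d (BAT depletion time constant / energy scale)\n", x$k))
  cat(sprintf("  c  = %g g, c1 = %g degC, c2 = %g degC per (cal g^-1 h^-1 g)\n",
              x$c, x$c1, x$c2))
  cat(sprintf("  Tp = %g degC, beta = %g, gamma = %g, n = %d pups\n",
              x$Tp, x$beta, x$gamma, x$n))
  invisible(x)
}

# Internal: accept either a huddle_constants object or NULL (-> defaults).
as_constants <- function(constants) {
  if (is.null(constants)) return(huddle_constants())
  if (!inherits(constants, "huddle_constants")) {
    rlang::abort("`constants` must be created with huddle_constants()")
  }
  constants
}
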