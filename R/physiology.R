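#' Developmental thermal-physiology curves
#'
#' Closed-form curves describing how mouse thermal physiology matures over the
#' first two months: depletion of brown adipose tissue (BAT), the metabolic
#' entropy it generates, the mass-specific metabolic rate, growth of muscle
#' and non-muscle mass, and the two competing components of the preferred
#' ambient temperature. All functions are vectorised over postnatal day `t`.
#'
#' The model in brief, with constants from [huddle_constants()]:
#' \itemize{
#'   \item BAT fraction `P = exp(-t/k)` decays from 1 at birth;
#'   \item entropy `S = -k P log(P)`, equivalently `t exp(-t/k)`, peaks at `t = k`;
#'   \item mass-specific metabolic rate `G = k (1 + S)` (cal g^-1 h^-1), where
#'     the unit term is the basal rate;
#'   \item muscle mass `M = k (1 - P)` grows towards `k` grams;
#'   \item non-muscle mass `N = c exp(-k T1)` so total mass `W = M + N`;
#'   \item warm deviation `T1 = c1 P` and cool deviation `T2 = c2 G N`, the
#'     preferred ambient temperature being `Tp + T1` early and `Tp - T2` late.
#' }
#'
#' @param t Postnatal day(s), non-negative, real-valued.
#' @param constants A [huddle_constants()] object (defaults used when `NULL`).
#'
#' @return A numeric vector the length of `t`.
#' @name physiology
#' @examples
#' bat_fraction(c(0, 8.31, 60))
#' metabolic_rate(8.31) # the developmental peak, k * (1 + k/e)
#' selected_temperature(c(0, 30, 60))
NULL

check_day <- function(t) {
  if (!is.numeric(t) || anyNA(t) || any(t < 0)) {
    rlang::abort("postnatal day `t` must be numeric and non-negative")
  }
  invisible(t)
}

#' @rdname physiology
#' @export
bat_fraction <- function(t, constants = NULL) {
  check_day(t)
  k <- as_constants(constants)$k
  exp(-t / k)
}

#' @rdname physiology
#' @export
bat_entropy <- function(t, constants = NULL) {
  check_day(t)
  k <- as_constants(constants)$k
  P <- exp(-t / k)
  # -k P log P; at t = 0, P = 1 and log(P) = 0 exactly, so S(0) = 0.
  # Once P underflows to 0 (t beyond ~5900 k) the limit P log P -> 0 applies.
  ifelse(P > 0, -k * P * log(P), 0) + 0 # "+ 0" turns IEEE -0 into +0 at t = 0
}

#' @rdname physiology
#' @export
metabolic_rate <- function(t, constants = NULL) {
  constants <- as_constants(constants)
  constants$k * (1 + bat_entropy(t, constants))
}

#' @rdname physiology
#' @export
muscle_mass <- function(t, constants = NULL) {
  constants <- as_constants(constants)
  constants$k * (1 - bat_fraction(t, constants))
}

#' @rdname physiology
#' @export
nonmuscle_mass <- function(t, constants = NULL) {
  constants <- as_constants(constants)
  constants$c * exp(-constants$k * warm_deviation(t, constants))
}

#' @rdname physiology
#' @export
body_mass <- function(t, constants = NULL) {
  constants <- as_constants(constants)
  muscle_mass(t, constants) + nonmuscle_mass(t, constants)
}

#' @rdname physiology
#' @export
warm_deviation <- function(t, constants = NULL) {
  constants <- as_constants(constants)
  constants$c1 * bat_fraction(t, constants)
}

#' @rdname physiology
#' @export
cool_deviation <- function(t, constants = NULL) {
  constants <- as_constants(constants)
  constants$c2 * metabolic_rate(t, constants) * nonmuscle_mass(t, constants)
}

#' Preferred ambient temperature across development
#'
#' The two thermoregulatory systems compete: the animal settles at `Tp + T1`
#' while the BAT-driven warm deviation dominates (`T1 >= T2`) and at
#' `Tp - T2` once the whole-body metabolic system takes over. This
#' dominant-deviation rule reproduces the early-warm (about 39 degC) to
#' late-cool (about 32 degC) switch seen on a thermocline.
#'
#' @inheritParams physiology
#' @return Numeric vector of selected ambient temperatures, degrees C.
#' @examples
#' selected_temperature(0)  # 39: neonates seek warmth
#' selected_temperature(60) # about 32: adults settle cooler
#' @export
selected_temperature <- function(t, constants = NULL) {
  constants <- as_constants(constants)
  T1 <- warm_deviation(t, constants)
  T2 <- cool_deviation(t, constants)
  ifelse(T1 >= T2, constants$Tp + T1, constants$Tp - T2)
}

#' Thermal huddling drive
#'
#' The scalar drive `beta * (T1 - T2)` that gates group joining: positive at
#' birth (contact is thermally rewarding) and negative in adulthood (contact
#' is thermally costly), crossing zero where the two preferred-temperature
#' deviations balance.
#'
#' @inheritParams physiology
#' @return Numeric vector, dimensionless.
#' @examples
#' huddling_drive(0)   # 0.6
#' huddling_drive(60)  # about -0.81
#' @export
huddling_drive <- function(t, constants = NULL) {
  constants <- as_constants(constants)
  constants$beta * (warm_deviation(t, constants) - cool_deviation(t, constants))
}

#' Evaluate all physiology curves on a day grid
#'
#' @param days Numeric vector of postnatal days (default a 0.1-day grid over
#'   0-60).
#' @inheritParams physiology
#' @return A tibble of class `huddle_curves` with columns `day`, `P` (BAT
#'   fraction), `S` (entropy), `G` (mass-specific metabolic rate), `M`, `N`,
#'   `W` (muscle, non-muscle, total mass, g), `T1`, `T2` (temperature
#'   deviations, degC), `selected_temp` (degC) and `drive`.
#' @examples
#' curves <- physiology_curves(days = 0:60)
#' curves[curves$day %in% c(0, 8, 15, 60), ]
#' @export
physiology_curves <- function(days = seq(0, 60, by = 0.1), constants = NULL) {
  constants <- as_constants(constants)
  check_day(days)
  out <- tibble::tibble(
    day = days,
    P = bat_fraction(days, constants),
    S = bat_entropy(days, constants),
    G = metabolic_rate(days, constants),
    M = muscle_mass(days, constants),
    N = nonmuscle_mass(days, constants),
    W = body_mass(days, constants),
    T1 = warm_deviation(days, constants),
    T2 = cool_deviation(days, constants),
    selected_temp = selected_temperature(days, constants),
    drive = huddling_drive(days, constants)
  )
  class(out) <- c("huddle_curves", class(out))
  attr(out, "constants") <- constants
  out
}

#' Postnatal day of peak mass-specific metabolic rate
#'
#' Locates the maximum of `G(t) = k (1 + S(t))` numerically: a coarse grid
#' scan over the interval followed by golden-section refinement
#' ([stats::optimize()]). Analytically the peak sits at `t = k`, the BAT
#' depletion time constant; this function recovers it without using that fact.
#'
#' @param constants A [huddle_constants()] object.
#' @param interval Search interval in days.
#' @param tol Absolute tolerance on the located day.
#' @return The maximising postnatal day, a single number.
#' @examples
#' metabolic_peak_day() # ~8.31
#' @export
metabolic_peak_day <- function(constants = NULL, interval = c(0, 60), tol = 1e-9) {
  constants <- as_constants(constants)
  grid <- seq(interval[1], interval[2], length.out = 601)
  g <- metabolic_rate(grid, constants)
  i <- which.max(g)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  stats::optimize(function(t) metabolic_rate(t, constants),
                  lower = lo, upper = hi, maximum = TRUE, tol = tol)$maximum
}

#' Day on which the cool deviation overtakes the warm deviation
#'
#' Solves `T1(t) = T2(t)` by root bracketing. Before this day the model animal
#' prefers warmth (`Tp + T1`) and the huddling drive is positive; after it the
#' preference flips to `Tp - T2` and the drive turns negative.
#'
#' @inheritParams metabolic_peak_day
#' @return The switch day (single number), or `NA` if no sign change occurs in
#'   `interval`.
#' @examples
#' temperature_switch_day() # ~16.5
#' @export
temperature_switch_day <- function(constants = NULL, interval = c(0, 60), tol = 1e-9) {
  constants <- as_constants(constants)
  f <- function(t) warm_deviation(t, constants) - cool_deviation(t, constants)
  if (f(interval[1]) * f(interval[2]) > 0) return(NA_real_)
  stats::uniroot(f, interval = interval, tol = tol)$root
}
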