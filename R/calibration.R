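#' Rescale raw BAT measurements to a unit decay curve
#'
#' Brown-adipose-tissue weights are reported as a percentage of body weight;
#' the model works with the affine rescaling that maps the birth anchor `p1`
#' to 1 and the adult anchor `p0` to 0: `(p - p0) / (p1 - p0)`.
#'
#' @param p Raw BAT percentage(s).
#' @param p0 Final (adult) anchor percentage.
#' @param p1 First (birth) anchor percentage.
#' @return Normalised fraction(s).
#' @examples
#' normalize_bat(c(4, 2.5, 1), p0 = 1, p1 = 4)
#' @export
normalize_bat <- function(p, p0, p1) {
  if (!is.numeric(p0) || !is.numeric(p1) || length(p0) != 1 || length(p1) != 1 ||
      isTRUE(all.equal(p0, p1))) {
    rlang::abort("anchors p0 and p1 must be distinct single numbers")
  }
  (p - p0) / (p1 - p0)
}

#' Generate a synthetic developmental dataset
#'
#' Evaluates the physiology curves on a day grid and adds independent
#' Gaussian noise, emulating the structure of classic developmental
#' measurements: scattered daily observations of BAT weight (percent of body
#' weight), mass-specific metabolic rate, body mass, and the ambient
#' temperature selected on a thermocline, over the first 60 postnatal days.
#' The generating constants and seed are recorded so that refits can be
#' scored against the truth.
#'
#' @param constants Generating [huddle_constants()].
#' @param days Observation days (default one per day, days 1-60).
#' @param noise Either a single fraction (noise sd as that fraction of each
#'   variable's dynamic range over `days`; default 0.05) or a named numeric
#'   vector of absolute sds for `bat_percent`, `metabolic_rate`, `body_mass`,
#'   `selected_temp`.
#' @param bat_anchors Named vector `c(p0 = , p1 = )`: adult and birth BAT
#'   percentages used to place the unit decay curve on the raw percent scale.
#' @param seed Integer seed; the dataset is deterministic given it.
#' @return A tibble of class `huddle_synth` with columns `day`, `bat_percent`,
#'   `metabolic_rate`, `body_mass`, `selected_temp`. The noiseless curves,
#'   generating constants, anchors, seed and noise sds are kept as attributes
#'   (`truth`, `constants`, `bat_anchors`, `seed`, `noise_sd`).
#' @examples
#' synth <- simulate_development_data(seed = 7)
#' head(synth)
#' @export
simulate_development_data <- function(constants = NULL, days = 1:60,
                                      noise = 0.05,
                                      bat_anchors = c(p0 = 1, p1 = 4),
                                      seed = NULL) {
  constants <- as_constants(constants)
  check_day(days)
  stopifnot("noise sds must be non-negative" = is.numeric(noise) && all(noise >= 0),
            "bat_anchors must name p0 and p1" = all(c("p0", "p1") %in% names(bat_anchors)))
  p0 <- bat_anchors[["p0"]]; p1 <- bat_anchors[["p1"]]
  truth <- tibble::tibble(
    day = days,
    bat_percent = p0 + (p1 - p0) * bat_fraction(days, constants),
    metabolic_rate = metabolic_rate(days, constants),
    body_mass = body_mass(days, constants),
    selected_temp = selected_temperature(days, constants)
  )
  vars <- c("bat_percent", "metabolic_rate", "body_mass", "selected_temp")
  if (length(noise) == 1 && is.null(names(noise))) {
    sds <- vapply(vars, function(v) noise * diff(range(truth[[v]])), 0)
  } else {
    if (!all(vars %in% names(noise))) {
      rlang::abort("named `noise` must supply an sd for every variable")
    }
    sds <- noise[vars]
  }
  if (!is.null(seed)) set.seed(seed)
  out <- truth
  for (v in vars) out[[v]] <- out[[v]] + stats::rnorm(nrow(out), sd = sds[[v]])
  class(out) <- c("huddle_synth", class(out))
  attr(out, "truth") <- truth
  attr(out, "constants") <- constants
  attr(out, "bat_anchors") <- bat_anchors
  attr(out, "seed") <- seed
  attr(out, "noise_sd") <- sds
  out
}

#' Refit the model constants from a developmental dataset
#'
#' Recovers `(k, c, c1, c2, Tp)` by staged nonlinear least squares, following
#' the order in which the quantities build on each other:
#' \enumerate{
#'   \item `k` (with nuisance anchors `p0`, `p1`) from the exponential decay
#'     of the raw BAT percentages;
#'   \item `c`, `c1` from the body-mass curve
#'     `W = k (1 - P) + c exp(-k c1 P)`, with `k` fixed at its stage-1 value;
#'   \item `c2`, `Tp` from the selected temperatures under the
#'     dominant-deviation rule. Because the warm branch `Tp + T1` dominates
#'     early and the cool branch `Tp - T2` late, branch membership is a
#'     threshold in age: the fit enumerates every candidate switch day,
#'     solves the (linear) least-squares problem for `(Tp, c2)` under each,
#'     keeps the best, then refines by reassigning each observation to its
#'     nearest branch until stable.
#' }
#' Staging avoids the identifiability tangle between `c2` and `Tp` that a
#' joint fit invites, and means noise in the mass or temperature columns
#' cannot perturb the estimate of `k`.
#'
#' @param data A data frame with columns `day`, `bat_percent`, `body_mass`,
#'   `selected_temp` (e.g. from [simulate_development_data()]); at least 10
#'   distinct days spanning both early (`< k`) and late (`> 3 k`) development.
#' @param fix_Tp Fix the target body temperature at this value instead of
#'   estimating it (`NULL`, the default, estimates it).
#' @return An object of class `huddle_fit`: estimates, per-stage RMS
#'   residuals, the estimated switch day, and the generating constants when
#'   `data` carries them.
#' @examples
#' synth <- simulate_development_data(noise = 0, seed = 1)
#' fit <- fit_constants(synth)
#' tidy(fit)
#' @export
fit_constants <- function(data, fix_Tp = NULL) {
  need <- c("day", "bat_percent", "body_mass", "selected_temp")
  if (!is.data.frame(data) || !all(need %in% names(data))) {
    rlang::abort(paste("`data` must contain columns", paste(need, collapse = ", ")))
  }
  d <- dplyr::arrange(tibble::as_tibble(data)[need], .data$day)
  if (length(unique(d$day)) < 10) {
    rlang::abort("need at least 10 distinct observation days to fit the model")
  }

  # stage 1: k and the BAT anchors from the raw decay
  f1 <- minpack.lm::nlsLM(
    bat_percent ~ p0 + (p1 - p0) * exp(-day / k),
    data = d,
    start = list(p0 = min(d$bat_percent), p1 = max(d$bat_percent), k = 10),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  k_hat <- stats::coef(f1)[["k"]]
  rms1 <- sqrt(mean(stats::resid(f1)^2))
  if (!any(d$day < k_hat) || !any(d$day > 3 * k_hat)) {
    rlang::abort(sprintf(
      "insufficient developmental coverage: need days both below k (%.2f) and above 3k (%.2f)",
      k_hat, 3 * k_hat))
  }

  # stage 2: c, c1 from the growth curve, k fixed
  P <- exp(-d$day / k_hat)
  d2 <- dplyr::mutate(d, P = P, M = k_hat * (1 - P))
  f2 <- minpack.lm::nlsLM(
    body_mass ~ M + c * exp(-k_hat * c1 * P),
    data = d2,
    start = list(c = max(d2$body_mass), c1 = 1),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  c_hat <- stats::coef(f2)[["c"]]
  c1_hat <- stats::coef(f2)[["c1"]]
  rms2 <- sqrt(mean(stats::resid(f2)^2))

  # stage 3: c2, Tp from the selected temperatures (piecewise linear in both)
  T1 <- c1_hat * P
  S <- -k_hat * P * log(P)
  G <- k_hat * (1 + S)
  N <- c_hat * exp(-k_hat * T1)
  x <- G * N
  y <- d$selected_temp

  solve_branch <- function(branch1) {
    # branch1: y ~ Tp + T1; branch2: y ~ Tp - c2 * x
    u <- ifelse(branch1, y - T1, y)
    v <- ifelse(branch1, 0, -x)
    if (is.null(fix_Tp)) {
      if (all(branch1) || !all(is.finite(v))) {
        # degenerate: no cool-branch points, c2 unidentified
        return(list(Tp = mean(u), c2 = NA_real_, sse = sum((u - mean(u))^2)))
      }
      fit <- stats::lm(u ~ v)
      co <- stats::coef(fit)
      list(Tp = co[[1]], c2 = if (length(co) > 1 && !is.na(co[[2]])) co[[2]] else NA_real_,
           sse = sum(stats::resid(fit)^2))
    } else {
      # minimise sum((u - Tp - c2*v)^2) with Tp fixed: c2 = sum(v*(u - Tp))/sum(v^2)
      c2 <- if (any(!branch1)) sum(v * (u - fix_Tp)) / sum(v^2) else NA_real_
      res <- u - fix_Tp - ifelse(is.na(c2), 0, c2) * v
      list(Tp = fix_Tp, c2 = c2, sse = sum(res^2))
    }
  }

  m <- nrow(d)
  best <- NULL
  for (j in 0:m) { # branch 1 for the first j observations (sorted by day)
    cand <- solve_branch(seq_len(m) <= j)
    if (is.null(best) || cand$sse < best$sse) {
      best <- cand
      best$j <- j
    }
  }
  # refine by nearest-branch reassignment
  branch1 <- seq_len(m) <= best$j
  for (iter in 1:25) {
    r1 <- abs(y - (best$Tp + T1))
    r2 <- if (is.na(best$c2)) rep(Inf, m) else abs(y - (best$Tp - best$c2 * x))
    new1 <- r1 <= r2
    if (identical(new1, branch1)) break
    branch1 <- new1
    best <- solve_branch(branch1)
  }
  rms3 <- sqrt(best$sse / m)
  switch_day <- if (any(branch1)) max(d$day[branch1]) else min(d$day)

  estimates <- tibble::tibble(
    term = c("k", "c", "c1", "c2", "Tp"),
    estimate = c(k_hat, c_hat, c1_hat, best$c2, best$Tp)
  )
  gen <- attr(data, "constants")
  if (inherits(gen, "huddle_constants")) {
    estimates$generating <- c(gen$k, gen$c, gen$c1, gen$c2, gen$Tp)
  }
  structure(
    list(
      estimates = estimates,
      stages = tibble::tibble(
        stage = c("bat_decay", "growth", "selected_temp"),
        rms = c(rms1, rms2, rms3),
        n = m
      ),
      switch_day = switch_day,
      n_days = length(unique(d$day)),
      fixed_Tp = fix_Tp
    ),
    class = "huddle_fit"
  )
}

#' @export
print.huddle_fit <- function(x, ...) {
  cat("<huddle_fit> staged least-squares calibration\n")
  est <- x$estimates
  for (i in seq_len(nrow(est))) {
    cat(sprintf("  %-3s = %.5g%s\n", est$term[i], est$estimate[i],
                if ("generating" %in% names(est))
                  sprintf("  (generating %.5g)", est$generating[i]) else ""))
  }
  cat(sprintf("  RMS residuals: BAT %.3g, growth %.3g, temperature %.3g (%d obs)\n",
              x$stages$rms[1], x$stages$rms[2], x$stages$rms[3], x$stages$n[1]))
  invisible(x)
}

#' Parameter estimates of a calibration fit
#'
#' @param x A `huddle_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, and `generating` (the
#'   true values) when the fitted dataset recorded its generating constants.
#' @method tidy huddle_fit
#' @export
tidy.huddle_fit <- function(x, ...) x$estimates

#' One-row summary of a calibration fit
#'
#' @param x A `huddle_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with per-stage RMS residuals, the estimated
#'   preferred-temperature switch day and the number of distinct days fitted.
#' @method glance huddle_fit
#' @export
glance.huddle_fit <- function(x, ...) {
  tibble::tibble(
    rms_bat = x$stages$rms[1],
    rms_growth = x$stages$rms[2],
    rms_temperature = x$stages$rms[3],
    switch_day = x$switch_day,
    n_days = x$n_days
  )
}
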