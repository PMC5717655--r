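#' Run a developmental huddling simulation
#'
#' The driver that couples the three layers of the model. A litter of `n`
#' pups starts postnatal day 0 joined in a single huddle. On each simulated
#' day the thermal drive `beta * (T1(t) - T2(t))` is evaluated from the
#' physiology curves, and `iters_per_day` Monte Carlo encounters ([mc_step()])
#' reconfigure the litter; the partition (and, in the learning condition, the
#' association matrix) carries over from day to day. In the `"learning"`
#' condition every encounter is a conditioning trial: the pairwise drive is
#' weighted by the partner's association for the initiator's odour
#' ([pairwise_drive()]) and the initiator's association is updated by the
#' Delta rule ([delta_update()]) with reward 1 on joining and 0 on detaching.
#' In the `"control"` condition all associations are fixed at 1 and no
#' learning occurs, so the drive is purely thermal.
#'
#' Replicate `r` uses seed `seed + r - 1`, so control and learning runs called
#' with the same `seed` are paired replicate-by-replicate.
#'
#' @param condition `"control"` (physiological huddling only) or `"learning"`
#'   (odour-heat conditioning enabled).
#' @param days Vector of postnatal days to simulate (default `0:60`).
#' @param iters_per_day Monte Carlo encounters per simulated day.
#' @param replicates Number of independent replicate litters.
#' @param seed Base integer seed.
#' @param estimator Group-size estimator, see [mean_group_size()].
#' @param symmetric_update Also apply the mirrored Delta update per encounter,
#'   see [delta_update()].
#' @param alpha_init Initial associative strength; defaults to 0 in the
#'   learning condition and 1 in the control.
#' @param alpha_snapshots Keep a per-day long-format snapshot of the
#'   association matrix (default: only in the learning condition).
#' @param constants A [huddle_constants()] object.
#'
#' @return An object of class `huddle_development` with components
#'   \describe{
#'     \item{stats}{tibble `day, condition, mean_group_size, sd, mean_rho`:
#'       per-day group size and join probability averaged over all encounters
#'       of the day and over replicates; `sd` is the between-replicate
#'       standard deviation of the daily mean group size.}
#'     \item{replicates}{the same statistics per replicate.}
#'     \item{alpha}{tibble `replicate, day, a, b, alpha` of association
#'       snapshots (or `NULL`).}
#'     \item{config}{the full configuration, including the seed.}
#'   }
#' @examples
#' dev <- run_development("control", days = 0:5, iters_per_day = 50,
#'                        replicates = 2, seed = 1)
#' tidy(dev)
#' @export
run_development <- function(condition = c("control", "learning"),
                            days = 0:60,
                            iters_per_day = 1000,
                            replicates = 10,
                            seed = 1,
                            estimator = c("groups", "pup_weighted"),
                            symmetric_update = FALSE,
                            alpha_init = NULL,
                            alpha_snapshots = NULL,
                            constants = NULL) {
  condition <- match.arg(condition)
  estimator <- match.arg(estimator)
  constants <- as_constants(constants)
  check_day(days)
  stopifnot(
    "iters_per_day must be >= 1" = iters_per_day >= 1,
    "replicates must be >= 1" = replicates >= 1,
    "at least one day is required" = length(days) >= 1,
    "seed must be a single finite integer" =
      is.numeric(seed) && length(seed) == 1 && is.finite(seed),
    "seed + replicates must stay below 2^31" = seed + replicates < 2^31
  )
  learning <- condition == "learning"
  if (is.null(alpha_init)) alpha_init <- if (learning) 0 else 1
  if (is.null(alpha_snapshots)) alpha_snapshots <- learning
  n <- constants$n
  base_drive <- huddling_drive(days, constants)
  pup_weighted <- estimator == "pup_weighted"

  rep_stats <- vector("list", replicates)
  snaps <- if (alpha_snapshots) vector("list", replicates) else NULL

  for (r in seq_len(replicates)) {
    set.seed(seed + r - 1)
    p0 <- huddle_partition(n, "together")
    grp <- unclass(p0)
    nextlab <- attr(p0, "nextlab")
    alpha <- init_association(n, alpha_init)
    gs <- rho_m <- numeric(length(days))
    day_snaps <- if (alpha_snapshots) vector("list", length(days)) else NULL
    for (di in seq_along(days)) {
      base <- base_drive[di]
      drive_fn <- function(a, b) alpha[b, a] * base
      sum_g <- 0
      sum_rho <- 0
      for (it in seq_len(iters_per_day)) {
        res <- encounter_step(grp, nextlab, drive_fn)
        grp <- res$grp
        nextlab <- res$nextlab
        if (learning) {
          alpha <- delta_update(alpha, res$a, res$b, as.numeric(res$joined),
                                constants, symmetric = symmetric_update)
        }
        sum_g <- sum_g + if (pup_weighted) {
          sum(tabulate(grp)^2) / n
        } else {
          n / length(unique(grp))
        }
        sum_rho <- sum_rho + res$rho
      }
      gs[di] <- sum_g / iters_per_day
      rho_m[di] <- sum_rho / iters_per_day
      if (alpha_snapshots) day_snaps[[di]] <- tidy_association(alpha, day = days[di])
    }
    rep_stats[[r]] <- tibble::tibble(
      replicate = r, day = days, condition = condition,
      mean_group_size = gs, mean_rho = rho_m
    )
    if (alpha_snapshots) {
      snaps[[r]] <- dplyr::mutate(dplyr::bind_rows(day_snaps), replicate = r, .before = 1)
    }
  }

  by_rep <- dplyr::bind_rows(rep_stats)
  stats <- by_rep |>
    dplyr::group_by(.data$day, .data$condition) |>
    dplyr::summarise(
      sd = stats::sd(.data$mean_group_size),
      mean_group_size = mean(.data$mean_group_size),
      mean_rho = mean(.data$mean_rho),
      .groups = "drop"
    ) |>
    dplyr::select("day", "condition", "mean_group_size", "sd", "mean_rho")

  structure(
    list(
      stats = stats,
      replicates = by_rep,
      alpha = if (alpha_snapshots) dplyr::bind_rows(snaps) else NULL,
      config = list(
        condition = condition, days = days, iters_per_day = iters_per_day,
        replicates = replicates, seed = seed, estimator = estimator,
        symmetric_update = symmetric_update, alpha_init = alpha_init,
        constants = constants
      )
    ),
    class = "huddle_development"
  )
}

#' @export
print.huddle_development <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<huddle_development> %s condition: %d pups, days %g-%g, %g iters/day, %g replicate(s), seed %g\n",
              cfg$condition, cfg$constants$n, min(cfg$days), max(cfg$days),
              cfg$iters_per_day, cfg$replicates, cfg$seed))
  last <- dplyr::slice_max(x$stats, .data$day, n = 1)
  cat(sprintf("  final day %g: mean group size %.2f (sd %.2f), mean rho %.3f\n",
              last$day, last$mean_group_size, last$sd, last$mean_rho))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy daily statistics of a developmental run
#'
#' @param x A `huddle_development` object.
#' @param ... Unused.
#' @return The replicate-averaged daily statistics tibble
#'   (`day, condition, mean_group_size, sd, mean_rho`).
#' @method tidy huddle_development
#' @export
tidy.huddle_development <- function(x, ...) x$stats

#' One-row summary of a developmental run
#'
#' @param x A `huddle_development` object.
#' @param ... Unused.
#' @return A one-row tibble: condition, configuration sizes, seed, final-day
#'   mean group size and mean join probability over the final 15 days.
#' @method glance huddle_development
#' @export
glance.huddle_development <- function(x, ...) {
  cfg <- x$config
  last <- dplyr::slice_max(x$stats, .data$day, n = 1)
  late <- steady_state_rho(x, window = c(max(cfg$days) - 15, max(cfg$days)))
  tibble::tibble(
    condition = cfg$condition,
    n_pups = cfg$constants$n,
    n_days = length(cfg$days),
    iters_per_day = cfg$iters_per_day,
    replicates = cfg$replicates,
    seed = cfg$seed,
    final_group_size = last$mean_group_size,
    late_mean_rho = late
  )
}

stats_of <- function(x, arg = "trace") {
  if (inherits(x, "huddle_development")) return(x$stats)
  if (is.data.frame(x) && all(c("day", "mean_group_size") %in% names(x))) {
    return(x)
  }
  rlang::abort(sprintf(
    "`%s` must be a huddle_development object or a data frame with columns day and mean_group_size", arg))
}

#' First day of persistent control/learning divergence
#'
#' Finds the smallest day `d` from which the learning condition's mean group
#' size exceeds the control's on every day of the window `[d, d + persistence)`.
#' The persistence window guards against single-day noise crossings; a
#' divergence is only reported if the full window fits inside the simulated
#' day range. The published calibration puts this transition from
#' physiological to filial huddling at around postnatal day 15.
#'
#' @param control,learning `huddle_development` objects (or their `stats`
#'   tibbles) on a common day grid.
#' @param persistence Window length in days.
#' @return The divergence day, or `NA` if the traces never separate
#'   persistently.
#' @export
detect_divergence_day <- function(control, learning, persistence = 5) {
  cs <- stats_of(control, "control")
  ls_ <- stats_of(learning, "learning")
  cs <- dplyr::arrange(cs, .data$day)
  ls_ <- dplyr::arrange(ls_, .data$day)
  if (!isTRUE(all.equal(cs$day, ls_$day))) {
    rlang::abort("control and learning traces must share the same day grid")
  }
  days <- cs$day
  exceeds <- ls_$mean_group_size > cs$mean_group_size
  for (i in seq_along(days)) {
    win <- days >= days[i] & days < days[i] + persistence
    if (max(days) < days[i] + persistence - 1) break # window no longer fits
    if (all(exceeds[win])) return(days[i])
  }
  NA_real_
}

#' Mean join probability late in development
#'
#' Averages the per-encounter join probability `rho` over a late window of
#' days and over replicates. In the learning condition the Delta rule drives
#' this towards the critical value 0.5 (group structure stays labile); in the
#' control condition it falls with the thermal drive to about 0.31 by day 60.
#'
#' @param x A `huddle_development` object, or a per-replicate stats tibble
#'   with columns `day` and `mean_rho`.
#' @param window Two-element numeric, inclusive day range (default the final
#'   15 days of the standard 0-60 run).
#' @return A single probability.
#' @export
steady_state_rho <- function(x, window = c(45, 60)) {
  tab <- if (inherits(x, "huddle_development")) x$replicates else x
  if (!is.data.frame(tab) || !all(c("day", "mean_rho") %in% names(tab))) {
    rlang::abort("`x` must be a huddle_development object or a data frame with columns day and mean_rho")
  }
  tab <- dplyr::filter(tab, .data$day >= window[1], .data$day <= window[2])
  if (nrow(tab) == 0) rlang::abort("no simulated days fall inside `window`")
  mean(tab$mean_rho)
}

#' Compare a control and a learning run
#'
#' @inheritParams detect_divergence_day
#' @param window Late-development day window for [steady_state_rho()] and the
#'   late group-size means.
#' @return A one-row tibble: `divergence_day`, `rho_learning`, `rho_control`,
#'   `late_group_size_learning`, `late_group_size_control`.
#' @export
compare_conditions <- function(control, learning, persistence = 5,
                               window = c(45, 60)) {
  late <- function(x) {
    s <- stats_of(x)
    mean(s$mean_group_size[s$day >= window[1] & s$day <= window[2]])
  }
  rho_of <- function(x) {
    if (inherits(x, "huddle_development")) steady_state_rho(x, window)
    else {
      s <- stats_of(x)
      mean(s$mean_rho[s$day >= window[1] & s$day <= window[2]])
    }
  }
  tibble::tibble(
    divergence_day = detect_divergence_day(control, learning, persistence),
    rho_learning = rho_of(learning),
    rho_control = rho_of(control),
    late_group_size_learning = late(learning),
    late_group_size_control = late(control)
  )
}
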