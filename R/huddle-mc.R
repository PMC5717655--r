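#' Litter partitions
#'
#' The state of the huddling simulator is a set partition of the `n` pups into
#' disjoint contact groups, stored as an integer vector of group labels (one
#' per pup). Labels are an internal detail: two partitions are equal whenever
#' they group the same pups together, regardless of labelling.
#'
#' @param n Number of pups (at least 2).
#' @param start `"together"` (all pups in one group, the simulator's initial
#'   state) or `"apart"` (all singletons).
#' @return A `huddle_partition`: an integer vector of length `n` of group
#'   labels.
#' @examples
#' huddle_partition(7)
#' partition_sizes(huddle_partition(7, "apart"))
#' @export
huddle_partition <- function(n, start = c("together", "apart")) {
  start <- match.arg(start)
  n <- as.integer(n)
  stopifnot("n must be at least 2" = length(n) == 1 && !is.na(n) && n >= 2)
  grp <- if (start == "together") rep(1L, n) else seq_len(n)
  new_partition(grp)
}

new_partition <- function(grp) {
  structure(as.integer(grp), nextlab = max(grp) + 1L, class = "huddle_partition")
}

#' Build a partition from an explicit list of groups
#'
#' @param groups A list of integer vectors that together contain each pup id
#'   `1..n` exactly once.
#' @return A `huddle_partition`.
#' @examples
#' as_huddle_partition(list(c(1, 2, 3, 4), c(5, 6, 7)))
#' @export
as_huddle_partition <- function(groups) {
  ids <- sort(unlist(groups))
  n <- length(ids)
  if (n < 2 || !identical(as.integer(ids), seq_len(n))) {
    rlang::abort("`groups` must partition pup ids 1..n (n >= 2) into disjoint groups")
  }
  grp <- integer(n)
  for (g in seq_along(groups)) grp[groups[[g]]] <- g
  new_partition(grp)
}

#' @export
print.huddle_partition <- function(x, ...) {
  gs <- partition_groups(x)
  cat("<huddle_partition> ", length(x), " pups in ", length(gs), " group(s): ",
      paste(vapply(gs, function(g) paste0("{", paste(g, collapse = ","), "}"), ""),
            collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @rdname huddle_partition
#' @param partition A `huddle_partition`.
#' @export
partition_sizes <- function(partition) {
  as.integer(sort(table(unclass(partition)), decreasing = TRUE))
}

#' @rdname huddle_partition
#' @export
partition_groups <- function(partition) {
  unname(split(seq_along(partition), unclass(partition)))
}

# Canonical restricted-growth labelling: groups numbered by first appearance.
# Makes equality and state tabulation label-invariant.
canonical_labels <- function(grp) {
  match(grp, unique(grp))
}

partition_key <- function(grp) {
  paste(canonical_labels(grp), collapse = ".")
}

#' @rdname huddle_partition
#' @param x,y Partitions to compare.
#' @export
same_partition <- function(x, y) {
  length(x) == length(y) && identical(canonical_labels(x), canonical_labels(y))
}

#' Average huddle size of a partition
#'
#' Two estimators are offered because "average group size" is ambiguous:
#' `"groups"` (the default) averages over groups, `n / #groups`; the
#' `"pup_weighted"` variant averages the size of the group each pup finds
#' itself in, `sum(sizes^2) / n`. Both equal 1 on all-singletons and `n` on a
#' single huddle.
#'
#' @param partition A `huddle_partition`.
#' @param estimator `"groups"` or `"pup_weighted"`.
#' @return A single number in `[1, n]`.
#' @examples
#' p <- as_huddle_partition(list(1:4, 5:7))
#' mean_group_size(p)                 # 3.5
#' mean_group_size(p, "pup_weighted") # 25/7
#' @export
mean_group_size <- function(partition, estimator = c("groups", "pup_weighted")) {
  estimator <- match.arg(estimator)
  sizes <- partition_sizes(partition)
  if (estimator == "groups") length(partition) / length(sizes)
  else sum(sizes^2) / length(partition)
}

#' Probability that an encounter joins two groups
#'
#' The logistic sigmoid `1 / (1 + exp(-T))` of the (association-weighted)
#' thermal drive `T`: at `T = 0` joining and detaching are equally likely and
#' group structure is maximally labile.
#'
#' @param drive Numeric vector of finite drive values.
#' @return Probabilities in (0, 1), the length of `drive`.
#' @examples
#' join_probability(c(-0.81, 0, 0.6))
#' @export
join_probability <- function(drive) {
  if (!is.numeric(drive) || anyNA(drive) || any(!is.finite(drive))) {
    rlang::abort("`drive` must be finite numeric")
  }
  stats::plogis(drive)
}

# Core encounter: pick initiator a uniformly; pick partner b uniformly from
# pups outside a's group (from all other pups when a single group holds the
# whole litter). Join the two groups with probability sigmoid(drive(a, b)),
# else detach a into a singleton. In the single-group case "join" is a no-op
# but still counts as a joined (rewarded) encounter; detaching a pup that is
# already a singleton leaves the grouping unchanged.
# Draws from R's RNG; callers control reproducibility with set.seed()/seed args.
encounter_step <- function(grp, nextlab, drive_fn) {
  n <- length(grp)
  a <- sample.int(n, 1L)
  in_a <- grp == grp[a]
  cand <- if (all(in_a)) seq_len(n)[-a] else which(!in_a)
  b <- cand[sample.int(length(cand), 1L)]
  d <- drive_fn(a, b)
  if (!is.finite(d)) rlang::abort("pairwise drive must be finite")
  rho <- 1 / (1 + exp(-d))
  joined <- stats::runif(1L) < rho
  if (joined) {
    if (grp[b] != grp[a]) grp[grp == grp[b]] <- grp[a]
  } else if (sum(grp == grp[a]) > 1L) {
    grp[a] <- nextlab
    nextlab <- nextlab + 1L
  }
  list(grp = grp, nextlab = nextlab, a = a, b = b, rho = rho, joined = joined)
}

#' One Monte Carlo reconfiguration step
#'
#' Performs a single random encounter on a litter partition: a randomly chosen
#' pup `a` meets a pup `b` from another group, and the two groups merge with
#' probability [join_probability()] of the pairwise drive, otherwise `a`
#' detaches to form a new singleton group. Uses R's global random number
#' stream; call [set.seed()] (or use the `seed` arguments of the run-level
#' functions) for reproducibility.
#'
#' @param partition A [huddle_partition()].
#' @param drive Either a single finite number (constant drive, as in the
#'   non-learning condition) or a function `(a, b) -> drive` giving the
#'   association-weighted drive of partner `b` for initiator `a`.
#' @return A list with elements `partition` (the updated `huddle_partition`)
#'   and `record`, a list with fields `a`, `b`, `rho` (the join probability
#'   used) and `joined` (logical outcome).
#' @examples
#' set.seed(1)
#' p <- huddle_partition(7, "apart")
#' step <- mc_step(p, drive = 0.6)
#' step$record$rho # 0.6457
#' @export
mc_step <- function(partition, drive) {
  if (!inherits(partition, "huddle_partition")) {
    rlang::abort("`partition` must be a huddle_partition")
  }
  drive_fn <- if (is.function(drive)) drive else {
    join_probability(drive) # validates finiteness
    function(a, b) drive
  }
  res <- encounter_step(unclass(partition), attr(partition, "nextlab"), drive_fn)
  out <- structure(res$grp, nextlab = res$nextlab, class = "huddle_partition")
  list(partition = out,
       record = list(a = res$a, b = res$b, rho = res$rho, joined = res$joined))
}

# All set partitions of n labelled pups, as canonical restricted-growth label
# vectors (group labels in order of first appearance).
enumerate_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, mx) {
    if (length(labels) == n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (g in seq_len(mx + 1L)) recurse(c(labels, g), max(mx, g))
  }
  recurse(1L, 1L)
  out
}

#' Exact stationary distribution of the huddling chain (small litters)
#'
#' For small `n` the encounter dynamics of [mc_step()] at a constant drive
#' form a finite Markov chain on the set partitions of the litter. This
#' builds the full transition matrix and returns its stationary distribution
#' (leading left eigenvector, normalised) — an exact reference against which
#' long simulated runs can be checked.
#'
#' @param n Litter size, between 2 and 5 (the state space is the Bell number
#'   of `n`, at most 52).
#' @param drive Constant scalar drive `T`.
#' @return A tibble with columns `state` (canonical label key, as used by
#'   [sample_partition_chain()]), `groups` (display string), `n_groups` and
#'   `probability`; the transition matrix is attached as attribute
#'   `transition`.
#' @examples
#' stationary_partition_distribution(2, drive = 0) # 0.5 / 0.5
#' @export
stationary_partition_distribution <- function(n, drive) {
  n <- as.integer(n)
  if (is.na(n) || n < 2 || n > 5) {
    rlang::abort("exact analysis is limited to litters of 2 to 5 pups")
  }
  join_probability(drive)
  rho <- 1 / (1 + exp(-drive))
  states <- enumerate_partitions(n)
  keys <- vapply(states, function(s) paste(s, collapse = "."), "")
  m <- length(states)
  P <- matrix(0, m, m, dimnames = list(keys, keys))
  for (i in seq_len(m)) {
    grp <- states[[i]]
    for (a in seq_len(n)) {
      in_a <- grp == grp[a]
      cand <- if (all(in_a)) seq_len(n)[-a] else which(!in_a)
      w <- 1 / (n * length(cand))
      for (b in cand) {
        # join outcome
        g2 <- grp
        if (g2[b] != g2[a]) g2[g2 == g2[b]] <- g2[a]
        j <- match(partition_key(g2), keys)
        P[i, j] <- P[i, j] + w * rho
        # detach outcome
        g3 <- grp
        if (sum(g3 == g3[a]) > 1L) g3[a] <- n + 1L
        d <- match(partition_key(g3), keys)
        P[i, d] <- P[i, d] + w * (1 - rho)
      }
    }
  }
  ev <- eigen(t(P))
  lead <- which.max(Re(ev$values))
  v <- Re(ev$vectors[, lead])
  v <- v / sum(v)
  out <- tibble::tibble(
    state = keys,
    groups = vapply(states, function(s) {
      paste(vapply(split(seq_len(n), s), function(g)
        paste0("{", paste(g, collapse = ","), "}"), ""), collapse = "")
    }, ""),
    n_groups = vapply(states, function(s) length(unique(s)), 1L),
    probability = v
  )
  attr(out, "transition") <- P
  out
}

#' Empirical state frequencies of a long simulated chain
#'
#' Runs the encounter dynamics for `steps` iterations at a constant drive and
#' tabulates how often each (label-invariant) partition state is visited after
#' a burn-in period. Companion to [stationary_partition_distribution()].
#'
#' @param n Litter size.
#' @param drive Constant scalar drive.
#' @param steps Number of post-burn-in steps to tabulate.
#' @param burn_in Steps discarded before tabulation.
#' @param seed Integer seed for reproducibility.
#' @param start Initial partition, `"together"` or `"apart"`.
#' @return A tibble with columns `state` and `frequency` (relative visit
#'   frequency, summing to 1).
#' @examples
#' sample_partition_chain(3, drive = 0, steps = 2000, seed = 1)
#' @export
sample_partition_chain <- function(n, drive, steps = 1e5, burn_in = 1000,
                                   seed = NULL, start = "together") {
  join_probability(drive)
  if (!is.null(seed)) set.seed(seed)
  p0 <- huddle_partition(n, start)
  grp <- unclass(p0)
  nextlab <- attr(p0, "nextlab")
  drive_fn <- function(a, b) drive
  counts <- new.env(parent = emptyenv())
  total <- burn_in + steps
  for (i in seq_len(total)) {
    res <- encounter_step(grp, nextlab, drive_fn)
    grp <- res$grp
    nextlab <- res$nextlab
    if (i > burn_in) {
      key <- partition_key(grp)
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
    }
  }
  keys <- ls(counts)
  tibble::tibble(
    state = keys,
    frequency = vapply(keys, function(k) counts[[k]], 0L) / steps
  )
}
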