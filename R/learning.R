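#' Association matrix among littermates
#'
#' Each pup `a` carries a directed associative strength `alpha[a, b]` for the
#' odour of each littermate `b`, learnt by odour-heat conditioning. In the
#' learning condition strengths start at 0 and adapt; in the non-learning
#' control they are fixed at 1, which reduces the pairwise drive to the pure
#' thermal drive. Values are unconstrained and can become negative (an
#' aversive association); the diagonal is unused and kept at 0.
#'
#' @param n Litter size.
#' @param value Initial off-diagonal strength (0 for the learning condition,
#'   1 for the control).
#' @return An `n x n` numeric matrix with zero diagonal.
#' @examples
#' init_association(7)           # learning condition start
#' init_association(7, value = 1) # control condition
#' @export
init_association <- function(n, value = 0) {
  n <- as.integer(n)
  stopifnot("n must be at least 2" = length(n) == 1 && !is.na(n) && n >= 2,
            "value must be a single finite number" =
              is.numeric(value) && length(value) == 1 && is.finite(value))
  alpha <- matrix(value, n, n)
  diag(alpha) <- 0
  alpha
}

check_pair <- function(alpha, a, b) {
  n <- nrow(alpha)
  if (!is.matrix(alpha) || ncol(alpha) != n) {
    rlang::abort("`alpha` must be a square matrix")
  }
  if (a == b) rlang::abort("a pup has no association with its own odour (a == b)")
  if (a < 1 || b < 1 || a > n || b > n) rlang::abort("pup ids out of range")
  invisible(NULL)
}

#' Association-weighted pairwise huddling drive
#'
#' The drive gating whether initiator `a` and partner `b` stay together:
#' `alpha[b, a] * (T1(t) - T2(t)) * beta`. The partner's association for the
#' *initiator's* odour does the weighting, so a littermate that has learnt to
#' like `a`'s smell keeps the pair together even after the thermal term turns
#' negative.
#'
#' @param a,b Pup ids (initiator, partner), distinct.
#' @param t Postnatal day.
#' @param alpha Association matrix, see [init_association()].
#' @param constants A [huddle_constants()] object.
#' @return A single drive value.
#' @examples
#' al <- init_association(7, value = 1)
#' pairwise_drive(1, 2, t = 0, alpha = al) # equals huddling_drive(0)
#' @export
pairwise_drive <- function(a, b, t, alpha, constants = NULL) {
  constants <- as_constants(constants)
  check_pair(alpha, a, b)
  alpha[b, a] * huddling_drive(t, constants)
}

#' Delta-rule update of one associative strength
#'
#' After an encounter between initiator `a` and partner `b` with reward
#' `r` (1 if their groups were combined, 0 if `a` detached), the strength
#' `alpha[a, b]` moves by `gamma * (r - sum_i alpha[a, i])`, where the sum
#' runs over *all* of `a`'s outgoing associations — the compound prediction
#' of the whole litter's odour, not just `b`'s. This compound term is what
#' keeps the total associative strength of each pup bounded and drives the
#' system towards the critical regime where join probability hovers near 0.5.
#'
#' @param alpha Association matrix.
#' @param a,b Pup ids (initiator, partner), distinct.
#' @param r Reward, exactly 0 or 1.
#' @param constants A [huddle_constants()] object (supplies `gamma`).
#' @param symmetric Also apply the mirrored update to `alpha[b, a]` using
#'   `b`'s own compound prediction. Off by default: the rule is written from
#'   the initiator's point of view.
#' @return The updated matrix; only entry `[a, b]` changes (and `[b, a]` when
#'   `symmetric = TRUE`).
#' @examples
#' al <- init_association(7)
#' al2 <- delta_update(al, 1, 2, r = 1)
#' al2[1, 2] # gamma = 0.001
#' @export
delta_update <- function(alpha, a, b, r, constants = NULL, symmetric = FALSE) {
  constants <- as_constants(constants)
  check_pair(alpha, a, b)
  if (!(length(r) == 1 && r %in% c(0, 1))) {
    rlang::abort("reward `r` must be exactly 0 or 1")
  }
  g <- constants$gamma
  alpha[a, b] <- alpha[a, b] + g * (r - sum(alpha[a, ]))
  if (symmetric) {
    alpha[b, a] <- alpha[b, a] + g * (r - sum(alpha[b, ]))
  }
  alpha
}

#' Long-format view of an association matrix
#'
#' @param alpha Association matrix.
#' @param day Optional postnatal day to stamp on every row.
#' @return A tibble with columns (`day`,) `a`, `b`, `alpha`, one row per
#'   ordered pair of distinct pups.
#' @examples
#' tidy_association(init_association(3, 1), day = 10)
#' @export
tidy_association <- function(alpha, day = NULL) {
  n <- nrow(alpha)
  out <- tibble::tibble(
    a = rep(seq_len(n), times = n),
    b = rep(seq_len(n), each = n),
    alpha = as.vector(alpha)
  )
  out <- dplyr::filter(out, .data$a != .data$b)
  if (!is.null(day)) out <- dplyr::mutate(out, day = day, .before = 1)
  out
}
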