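#' The standardized log-likelihood person-fit statistic lz
#'
#' For a dichotomous response vector under the 2PL,
#' `lz = sum_j w_j (u_j - P_j) / sqrt(sum_j w_j^2 P_j (1 - P_j))` with log-odds
#' weights `w_j = log(P_j / (1 - P_j))`. Large negative values indicate a
#' response pattern less likely than the model expects at that ability.
#'
#' @param u Binary response vector.
#' @param theta Ability at which to evaluate the statistic.
#' @param a,b 2PL item parameters.
#' @return A single numeric; `NA` with attribute `degenerate_reason` when the
#'   variance term is zero (e.g. theta equals every difficulty).
#' @export
compute_lz <- function(u, theta, a, b) {
  stopifnot(length(a) == length(u), length(b) == length(u), all(a > 0))
  P <- stats::plogis(a * (theta - b))
  w <- stats::qlogis(P)
  denom2 <- sum(w^2 * P * (1 - P))
  if (denom2 <= 1e-12) return(degenerate_stat("zero_variance"))
  sum(w * (u - P)) / sqrt(denom2)
}

degenerate_stat <- function(reason) {
  structure(NA_real_, degenerate_reason = reason)
}

#' Components of the Snijders correction to lz
#'
#' When ability is estimated rather than known, the naive lz is mis-calibrated.
#' The correction replaces the weights by `w*_j = w_j - c_J r_j`, where under
#' maximum likelihood estimation the estimating-equation weights are
#' `r_j = a_j` (the derivative of the log-odds) with offset `r_0 = 0`, and
#' `c_J = sum_j P'_j w_j / sum_j P'_j r_j` with `P'_j = a_j P_j (1 - P_j)`.
#'
#' @param theta_hat The ability estimate (MLE) for the person.
#' @param a,b 2PL item parameters.
#' @return A list with `P`, `Pprime`, `w`, `r`, `r0`, `cJ`, `w_star` and a
#'   `degenerate_reason` (`NA_character_` when well defined).
#' @export
lzstar_components <- function(theta_hat, a, b) {
  stopifnot(length(a) == length(b), all(a > 0))
  P <- stats::plogis(a * (theta_hat - b))
  w <- stats::qlogis(P)
  Pprime <- a * P * (1 - P)
  r <- a
  denom <- sum(Pprime * r)
  if (abs(denom) <= 1e-12) {
    return(list(P = P, Pprime = Pprime, w = w, r = r, r0 = 0,
                cJ = NA_real_, w_star = rep(NA_real_, length(a)),
                degenerate_reason = "zero_information"))
  }
  cJ <- sum(Pprime * w) / denom
  w_star <- w - cJ * r
  reason <- if (sum(w_star^2 * P * (1 - P)) <= 1e-12) "zero_variance" else NA_character_
  list(P = P, Pprime = Pprime, w = w, r = r, r0 = 0,
       cJ = cJ, w_star = w_star, degenerate_reason = reason)
}

#' The Snijders-corrected person-fit statistic lz*
#'
#' lz evaluated at the ability MLE with the corrected weights `w*_j` of
#' [lzstar_components()]; asymptotically standard normal under the model even
#' though theta is estimated.
#'
#' @inheritParams compute_lz
#' @param theta_hat Ability MLE.
#' @return A single numeric; `NA` with `degenerate_reason` when undefined.
#' @export
compute_lz_star <- function(u, theta_hat, a, b) {
  stopifnot(length(a) == length(u), length(b) == length(u))
  comp <- lzstar_components(theta_hat, a, b)
  if (!is.na(comp$degenerate_reason)) return(degenerate_stat(comp$degenerate_reason))
  denom2 <- sum(comp$w_star^2 * comp$P * (1 - comp$P))
  sum(comp$w_star * (u - comp$P)) / sqrt(denom2)
}

#' Flag respondents as non-effortful from a person-fit statistic
#'
#' A person is flagged when the statistic falls strictly below the critical
#' value (default -1.645, the one-sided 5% normal quantile). Exactly critical
#' values are not flagged; `NA` statistics yield `NA` flags.
#'
#' @param stats_vec Numeric vector of person-fit statistics.
#' @param critical Critical value (default -1.645).
#' @return Logical vector, `TRUE` = flagged non-effortful.
#' @export
flag_noneffortful <- function(stats_vec, critical = -1.645) {
  stats_vec < critical
}

#' Person-fit analysis of a response matrix
#'
#' Estimates each person's ability by maximum likelihood under the supplied
#' item parameters, then computes lz and the Snijders-corrected lz* and flags
#' persons below the critical value. Persons with perfect or zero scores are
#' evaluated at the clamped ability and marked by `status`.
#'
#' @param U Binary I x J response matrix.
#' @param items Item parameters (tibble with `a`/`b` or `a_hat`/`b_hat`, or an
#'   `irt_2pl_fit`).
#' @param critical Flagging threshold on lz* (default -1.645).
#' @param theta_max Ability clamp for perfect/zero scores.
#' @param theta_hat Optional precomputed ability tibble from
#'   [estimate_abilities()]; supplying it skips re-estimation but the values
#'   must come from the same item parameters.
#' @return Tibble with `person`, `theta_hat`, `status`, `lz`, `lz_star`,
#'   `flagged`, `degenerate_reason`.
#' @examples
#' sim <- simulate_effort_data(effort_config(I = 300, J = 20, seed = 3))
#' pf <- person_fit(sim$U, sim$items)
#' mean(pf$flagged)
#' @export
person_fit <- function(U, items, critical = -1.645, theta_max = 4,
                       theta_hat = NULL) {
  ab <- item_ab(items)
  U <- as.matrix(U)
  if (is.null(theta_hat)) theta_hat <- estimate_abilities(U, items, theta_max)
  stopifnot(nrow(theta_hat) == nrow(U))

  n <- nrow(U)
  lz <- lzs <- numeric(n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    th <- theta_hat$theta_hat[i]
    v <- compute_lz(U[i, ], th, ab$a, ab$b)
    vs <- compute_lz_star(U[i, ], th, ab$a, ab$b)
    lz[i] <- as.numeric(v)
    lzs[i] <- as.numeric(vs)
    r <- attr(vs, "degenerate_reason")
    if (!is.null(r)) reason[i] <- r
  }
  out <- theta_hat[c("person", "theta_hat", "status")]
  out$lz <- lz
  out$lz_star <- lzs
  out$flagged <- flag_noneffortful(lzs, critical)
  out$degenerate_reason <- reason
  out
}
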