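#' Simulation configuration for mixed effortful / rapid-guessing data
#'
#' Bundles every knob of the generating model: a two-parameter logistic (2PL)
#' model for accuracy and a lognormal model for response times at level one,
#' a bivariate normal over the person parameters (ability theta, latent speed
#' tau) at level two, and a rapid-guessing mixture layered on top. A fraction
#' `pi` of persons is non-effortful; each such person answers a fraction
#' `pi_i` of items (their severity) by rapid guessing: chance-level accuracy
#' `guess_p` and short log-times drawn from N(`noneffort_logt_mean`, 0.25).
#'
#' Non-effortful persons are drawn preferentially from the slow: 60% from the
#' lowest third of true tau, 30% from the middle, 10% from the top.
#'
#' @param I Number of persons.
#' @param J Number of items.
#' @param pi Non-effort prevalence, proportion of persons in `[0, 1]`.
#' @param severity `"low"` (per-person severity `pi_i ~ U(0, 0.25)`) or
#'   `"high"` (`pi_i ~ U(0.5, 0.75)`).
#' @param drt `"low"` (non-effortful log-seconds `~ N(-1, 0.25)`) or `"high"`
#'   (`~ N(-2, 0.25)`); variance 0.25 in both cases.
#' @param mu Length-2 person mean vector `(mu_theta, mu_tau)`. The default
#'   `c(0, -3.5)` puts effortful item times near `exp(3.5)` ~ 33 s, well above
#'   rapid-guess times of well under a second.
#' @param Sigma 2x2 person covariance matrix; must be symmetric positive
#'   definite. The default gives `cor(theta, tau) = 0.70`.
#' @param guess_p Success probability of a rapid guess (chance level for
#'   4-option multiple choice: 0.25).
#' @param severity_mode `"count"` (each non-effortful person guesses on a
#'   uniformly chosen subset of exactly `round(pi_i * J)` items) or
#'   `"bernoulli"` (each item independently guessed with probability `pi_i`).
#' @param seed Integer seed; every draw of the simulator is a deterministic
#'   function of the config including this seed.
#' @return A list of class `"effort_config"`.
#' @export
effort_config <- function(I = 1000L, J = 30L, pi = 0.2,
                          severity = c("high", "low"),
                          drt = c("low", "high"),
                          mu = c(0, -3.5),
                          Sigma = matrix(c(1, 0.25, 0.25, 0.1275), 2, 2),
                          guess_p = 0.25,
                          severity_mode = c("count", "bernoulli"),
                          seed = 1L) {
  severity <- match.arg(severity)
  drt <- match.arg(drt)
  severity_mode <- match.arg(severity_mode)
  if (length(I) != 1L || I < 1) stop("`I` must be a positive count", call. = FALSE)
  if (length(J) != 1L || J < 1) stop("`J` must be a positive count", call. = FALSE)
  if (pi < 0 || pi > 1) stop("`pi` must lie in [0, 1]", call. = FALSE)
  if (guess_p <= 0 || guess_p >= 1) stop("`guess_p` must lie in (0, 1)", call. = FALSE)
  if (length(mu) != 2L) stop("`mu` must have length 2", call. = FALSE)
  check_sigma(Sigma)
  structure(
    list(I = as.integer(I), J = as.integer(J), pi = pi,
         severity = severity, drt = drt,
         mu = as.numeric(mu), Sigma = Sigma, guess_p = guess_p,
         severity_mode = severity_mode, seed = as.integer(seed)),
    class = "effort_config"
  )
}

check_sigma <- function(Sigma) {
  if (!is.matrix(Sigma) || any(dim(Sigma) != 2L))
    stop("`Sigma` must be a 2x2 matrix", call. = FALSE)
  if (max(abs(Sigma - t(Sigma))) > 1e-12)
    stop("`Sigma` must be symmetric", call. = FALSE)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("`Sigma` must be positive definite", call. = FALSE)
  invisible(Sigma)
}

#' @export
print.effort_config <- function(x, ...) {
  cat(sprintf(
    "<effort_config> I=%d J=%d pi=%.2f severity=%s dRT=%s mu=(%g, %g) seed=%d\n",
    x$I, x$J, x$pi, x$severity, x$drt, x$mu[1], x$mu[2], x$seed))
  invisible(x)
}

severity_bounds <- function(severity) {
  switch(severity, low = c(0, 0.25), high = c(0.5, 0.75))
}

noneffort_logt_mean <- function(drt) {
  switch(drt, low = -1, high = -2)
}

#' Draw item parameters of the joint accuracy / response-time model
#'
#' Items carry a 2PL discrimination `a ~ U(1, 2.5)` and difficulty
#' `b ~ N(0, 1)`, plus lognormal response-time parameters: time discrimination
#' `alpha ~ U(1.5, 2.5)` (reciprocal SD of log-seconds) and time intensity
#' `beta ~ U(-0.2, 0.2)` (typical log-seconds at tau = 0).
#'
#' @param J Number of items (positive).
#' @return A tibble with columns `item`, `a`, `b`, `alpha`, `beta`.
#' @export
draw_item_parameters <- function(J) {
  if (length(J) != 1L || J < 1) stop("`J` must be a positive count", call. = FALSE)
  J <- as.integer(J)
  tibble::tibble(
    item  = seq_len(J),
    a     = stats::runif(J, 1, 2.5),
    b     = stats::rnorm(J, 0, 1),
    alpha = stats::runif(J, 1.5, 2.5),
    beta  = stats::runif(J, -0.2, 0.2)
  )
}

#' Draw person parameters (ability, latent speed)
#'
#' Persons are i.i.d. bivariate normal: `(theta, tau) ~ N(mu, Sigma)`.
#'
#' @param I Number of persons (positive).
#' @param mu Length-2 mean vector `(mu_theta, mu_tau)`.
#' @param Sigma 2x2 symmetric positive-definite covariance.
#' @return A tibble with columns `person`, `theta`, `tau`.
#' @export
draw_person_parameters <- function(I, mu = c(0, -3.5),
                                   Sigma = matrix(c(1, 0.25, 0.25, 0.1275), 2, 2)) {
  if (length(I) != 1L || I < 1) stop("`I` must be a positive count", call. = FALSE)
  check_sigma(Sigma)
  I <- as.integer(I)
  L <- chol(Sigma)
  Z <- matrix(stats::rnorm(2L * I), I, 2L)
  XY <- sweep(Z %*% L, 2L, as.numeric(mu), "+")
  tibble::tibble(person = seq_len(I), theta = XY[, 1], tau = XY[, 2])
}

#' Assign non-effortful persons and their rapid-guessed items
#'
#' Marks exactly `round(pi * I)` persons as non-effortful, stratified by true
#' latent speed: 60% from the lowest tau tercile, 30% from the middle, 10%
#' from the top (rounding residue goes to the lowest tercile). Each
#' non-effortful person draws a severity `pi_i` from the severity
#' distribution and, under the default count mode, a uniformly random subset
#' of `round(pi_i * J)` items to answer by rapid guessing. A person whose
#' severity rounds to zero items keeps the non-effortful label.
#'
#' @param persons Tibble from [draw_person_parameters()].
#' @param config An [effort_config()].
#' @return A list with `is_noneffortful` (logical I), `pi_i` (numeric I, `NA`
#'   for effortful persons) and `noneffort_mask` (logical I x J; `TRUE` where
#'   the cell is rapid-guessed).
#' @export
assign_noneffort <- function(persons, config) {
  I <- nrow(persons)
  J <- config$J
  n_ne <- round(config$pi * I)
  is_ne <- rep(FALSE, I)
  pi_i <- rep(NA_real_, I)
  mask <- matrix(FALSE, I, J)

  if (n_ne > 0) {
    # tercile membership on true tau, ties broken by person index
    ord <- order(persons$tau, persons$person)
    third <- floor(I / 3)
    sizes <- c(third, third, I - 2L * third)
    terc <- integer(I)
    terc[ord] <- rep(1:3, times = sizes)

    want <- c(round(0.6 * n_ne), round(0.3 * n_ne), round(0.1 * n_ne))
    want[1] <- want[1] + (n_ne - sum(want))   # residual to the lowest tercile
    if (any(want > sizes))
      stop("requested tercile count exceeds tercile size", call. = FALSE)

    chosen <- unlist(lapply(1:3, function(k) {
      pool <- which(terc == k)
      if (want[k] == 0) integer(0) else pool[sample.int(length(pool), want[k])]
    }), use.names = FALSE)
    is_ne[chosen] <- TRUE

    bnd <- severity_bounds(config$severity)
    pi_i[chosen] <- stats::runif(length(chosen), bnd[1], bnd[2])
    for (i in chosen) {
      if (config$severity_mode == "count") {
        n_items <- round(pi_i[i] * J)
        if (n_items > 0) mask[i, sample.int(J, n_items)] <- TRUE
      } else {
        mask[i, ] <- stats::runif(J) < pi_i[i]
      }
    }
  }
  list(is_noneffortful = is_ne, pi_i = pi_i, noneffort_mask = mask)
}

#' Generate the response and response-time matrices
#'
#' Effortful cells follow the hierarchical model: `U ~ Bernoulli(logistic(
#' a_j (theta_i - b_j)))` and `log T ~ N(beta_j - tau_i, alpha_j^-2)`.
#' Rapid-guessed cells follow the mixture component: `U ~ Bernoulli(guess_p)`
#' and `log T ~ N(m, 0.25)` with `m = -1` (dRT low) or `-2` (dRT high).
#'
#' @param items Tibble from [draw_item_parameters()].
#' @param persons Tibble from [draw_person_parameters()].
#' @param assignment List from [assign_noneffort()].
#' @param config An [effort_config()].
#' @return List with binary matrix `U` and positive time matrix `T_mat`
#'   (seconds), both I x J.
#' @export
generate_observations <- function(items, persons, assignment, config) {
  I <- nrow(persons); J <- nrow(items)
  stopifnot(nrow(assignment$noneffort_mask) == I,
            ncol(assignment$noneffort_mask) == J)
  eta <- outer(persons$theta, items$b, "-") *
    matrix(items$a, I, J, byrow = TRUE)
  P <- stats::plogis(eta)
  mlog <- outer(-persons$tau, items$beta, "+")           # beta_j - tau_i
  slog <- matrix(1 / items$alpha, I, J, byrow = TRUE)    # SD = alpha^-1

  mask <- assignment$noneffort_mask
  P[mask] <- config$guess_p
  mlog[mask] <- noneffort_logt_mean(config$drt)
  slog[mask] <- sqrt(0.25)

  U <- matrix(as.integer(stats::runif(I * J) < P), I, J)
  T_mat <- exp(matrix(stats::rnorm(I * J), I, J) * slog + mlog)
  dimnames(U) <- dimnames(T_mat) <-
    list(persons$person, paste0("item", items$item))
  list(U = U, T_mat = T_mat)
}

#' Simulate a complete mixed effortful / rapid-guessing dataset
#'
#' Composes the four draws — item parameters, person parameters, non-effort
#' assignment, observations — under a single seed, retaining the full
#' generating truth for evaluation.
#'
#' @param config An [effort_config()].
#' @return An object of class `"effort_sim"`: list with `U`, `T_mat`,
#'   `items`, `persons` (tibble incl. truth columns `is_noneffortful`,
#'   `pi_i`), `mask`, `config`.
#' @examples
#' sim <- simulate_effort_data(effort_config(I = 200, J = 15, seed = 7))
#' table(sim$persons$is_noneffortful)
#' @export
simulate_effort_data <- function(config = effort_config()) {
  stopifnot(inherits(config, "effort_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  items <- draw_item_parameters(config$J)
  persons <- draw_person_parameters(config$I, config$mu, config$Sigma)
  assignment <- assign_noneffort(persons, config)
  obs <- generate_observations(items, persons, assignment, config)

  persons$is_noneffortful <- assignment$is_noneffortful
  persons$pi_i <- assignment$pi_i
  structure(
    list(U = obs$U, T_mat = obs$T_mat, items = items, persons = persons,
         mask = assignment$noneffort_mask, config = config),
    class = "effort_sim"
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.effort_sim <- function(x, ...) {
  cat(sprintf(
    "<effort_sim> %d persons x %d items; %d non-effortful (pi=%.2f, %s severity, dRT %s)\n",
    x$config$I, x$config$J, sum(x$persons$is_noneffortful),
    x$config$pi, x$config$severity, x$config$drt))
  invisible(x)
}

#' @rdname simulate_effort_data
#' @param x An `effort_sim` object.
#' @param ... Unused.
#' @return `tidy.effort_sim()`: one row per person with truth labels and
#'   observed summaries (proportion correct, mean response time in seconds).
#' @method tidy effort_sim
#' @export
tidy.effort_sim <- function(x, ...) {
  dplyr::mutate(x$persons,
                prop_correct = rowMeans(x$U),
                mean_rt = rowMeans(x$T_mat))
}

#' Write / read a simulated dataset as plain CSV files
#'
#' Writes `responses.csv` and `times.csv` (person-ID first column, item IDs in
#' the header), `items.csv`, `truth.csv` and `mask.csv` into `dir`.
#'
#' @param sim An `effort_sim` object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_effort_data <- function(sim, dir) {
  stopifnot(inherits(sim, "effort_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(responses = file.path(dir, "responses.csv"),
             times = file.path(dir, "times.csv"),
             items = file.path(dir, "items.csv"),
             truth = file.path(dir, "truth.csv"),
             mask = file.path(dir, "mask.csv"))
  as_tbl <- function(M) {
    tibble::as_tibble(as.data.frame(M)) |>
      dplyr::mutate(person = sim$persons$person, .before = 1)
  }
  readr::write_csv(as_tbl(sim$U), paths["responses"])
  readr::write_csv(as_tbl(sim$T_mat), paths["times"])
  readr::write_csv(as_tbl(sim$mask * 1L), paths["mask"])
  readr::write_csv(sim$items, paths["items"])
  readr::write_csv(sim$persons, paths["truth"])
  invisible(paths)
}
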