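#' 2PL item response probability
#'
#' Probability of a correct response under the two-parameter logistic model,
#' `P(theta) = logistic(a (theta - b))`.
#'
#' @param theta Ability value(s).
#' @param a Discrimination (> 0).
#' @param b Difficulty.
#' @return Probabilities in (0, 1), vectorized over the inputs.
#' @export
prob_2pl <- function(theta, a, b) {
  if (any(a <= 0)) stop("discrimination `a` must be positive", call. = FALSE)
  stats::plogis(a * (theta - b))
}

#' Calibration settings for the marginal maximum likelihood EM
#'
#' @param n_quadrature Number of fixed Gauss points for the latent ability
#'   (equally spaced, standard-normal weights, renormalized).
#' @param quad_range Interval covered by the quadrature grid.
#' @param tol EM stops when the largest absolute change in any item parameter
#'   falls below `tol`.
#' @param max_iter Iteration cap.
#' @param a_bounds,b_bounds Box constraints on the item estimates; items hit
#'   by a bound (e.g. constant columns) are reported with `converged = FALSE`.
#' @return A list of class `"calib_settings"`.
#' @export
calib_settings <- function(n_quadrature = 61L, quad_range = c(-6, 6),
                           tol = 1e-4, max_iter = 500L,
                           a_bounds = c(0.2, 5), b_bounds = c(-6, 6)) {
  stopifnot(tol > 0, n_quadrature >= 3, quad_range[1] < quad_range[2],
            a_bounds[1] < a_bounds[2], b_bounds[1] < b_bounds[2])
  structure(list(n_quadrature = as.integer(n_quadrature),
                 quad_range = quad_range, tol = tol,
                 max_iter = as.integer(max_iter),
                 a_bounds = a_bounds, b_bounds = b_bounds),
            class = "calib_settings")
}

quad_grid <- function(settings) {
  x <- seq(settings$quad_range[1], settings$quad_range[2],
           length.out = settings$n_quadrature)
  w <- stats::dnorm(x)
  list(nodes = x, weights = w / sum(w))
}

#' Calibrate 2PL item parameters by marginal maximum likelihood
#'
#' Bock-Aitkin EM with a fixed quadrature grid and a standard-normal latent
#' density. The E-step computes each person's posterior over the grid; the
#' M-step refits each item's slope and intercept by Newton iterations on the
#' expected complete-data logistic likelihood. The marginal log-likelihood is
#' non-decreasing across iterations. Starting values are deterministic
#' (`a = 1`, `b` from the probit transform of the item proportion correct),
#' so repeated runs on the same input give identical estimates.
#'
#' @param U Binary I x J response matrix (no missing values).
#' @param settings A [calib_settings()] list.
#' @return An object of class `"irt_2pl_fit"` with per-item estimates
#'   (`tidy()` it for a tibble), the final marginal log-likelihood, iteration
#'   count, and the log-likelihood trace.
#' @examples
#' sim <- simulate_effort_data(effort_config(I = 300, J = 10, pi = 0, seed = 2))
#' fit <- fit_2pl(sim$U)
#' tidy(fit)
#' @export
fit_2pl <- function(U, settings = calib_settings()) {
  U <- as.matrix(U)
  if (!all(U %in% c(0L, 1L))) stop("`U` must be binary", call. = FALSE)
  if (nrow(U) < 2L || ncol(U) < 2L)
    stop("need at least 2 persons and 2 items", call. = FALSE)
  storage.mode(U) <- "double"
  I <- nrow(U); J <- ncol(U)
  q <- quad_grid(settings)
  K <- length(q$nodes)

  pbar <- colMeans(U)
  degenerate_item <- pbar <= 0 | pbar >= 1
  if (any(degenerate_item))
    warning("constant response column(s): ",
            paste(which(degenerate_item), collapse = ", "),
            "; estimates pinned at bounds")
  a <- rep(1, J)
  b <- -stats::qnorm(pmin(pmax(pbar, 1 / (2 * I)), 1 - 1 / (2 * I)))
  b <- clamp(b, settings$b_bounds[1], settings$b_bounds[2])

  loglik_trace <- numeric(0)
  n_iter <- 0L
  repeat {
    n_iter <- n_iter + 1L
    # E-step: posterior over quadrature nodes per person
    logP <- t(stats::plogis(outer(q$nodes, b, "-") * rep(a, each = K),
                            log.p = TRUE))                      # J x K log P
    logQ <- t(stats::plogis(outer(q$nodes, b, "-") * rep(a, each = K),
                            log.p = TRUE, lower.tail = FALSE))  # J x K log(1-P)
    LL <- U %*% logP + (1 - U) %*% logQ                          # I x K
    LL <- sweep(LL, 2L, log(q$weights), "+")
    m <- apply(LL, 1L, max)
    W <- exp(LL - m)
    rs <- rowSums(W)
    loglik <- sum(m + log(rs))
    post <- W / rs                                               # I x K

    nk <- colSums(post)                # expected persons at node k
    rk <- crossprod(post, U)           # K x J expected corrects

    a_new <- a; b_new <- b
    for (j in seq_len(J)) {
      if (degenerate_item[j]) {
        b_new[j] <- if (pbar[j] >= 1) settings$b_bounds[1] else settings$b_bounds[2]
        a_new[j] <- settings$a_bounds[1]
        next
      }
      fit_j <- mstep_item(q$nodes, nk, rk[, j], a[j], b[j], settings)
      a_new[j] <- fit_j[1]; b_new[j] <- fit_j[2]
    }

    delta <- max(abs(c(a_new - a, b_new - b)))
    a <- a_new; b <- b_new
    loglik_trace <- c(loglik_trace, loglik)
    if (delta < settings$tol || n_iter >= settings$max_iter) break
  }

  at_bound <- a <= settings$a_bounds[1] + 1e-9 | a >= settings$a_bounds[2] - 1e-9 |
    b <= settings$b_bounds[1] + 1e-9 | b >= settings$b_bounds[2] - 1e-9
  structure(
    list(a_hat = a, b_hat = b,
         item_converged = !(degenerate_item | at_bound),
         converged = n_iter < settings$max_iter,
         n_iter = n_iter, loglik = loglik_trace[length(loglik_trace)],
         loglik_trace = loglik_trace, n_persons = I, n_items = J,
         settings = settings),
    class = "irt_2pl_fit"
  )
}

# Newton ascent of the expected logistic likelihood for one item, in
# slope-intercept parameterization eta = a*x + c; halving safeguard keeps the
# objective non-decreasing, box constraints applied on exit.
mstep_item <- function(x, nk, rj, a0, b0, settings) {
  par <- c(a0, -a0 * b0)
  obj <- function(p) {
    eta <- p[1] * x + p[2]
    sum(rj * stats::plogis(eta, log.p = TRUE) +
          (nk - rj) * stats::plogis(eta, log.p = TRUE, lower.tail = FALSE))
  }
  f0 <- obj(par)
  for (it in 1:50) {
    eta <- par[1] * x + par[2]
    mu <- stats::plogis(eta)
    wv <- nk * mu * (1 - mu)
    g <- c(sum((rj - nk * mu) * x), sum(rj - nk * mu))
    H <- -matrix(c(sum(wv * x^2), sum(wv * x), sum(wv * x), sum(wv)), 2, 2)
    step <- tryCatch(solve(H, g), error = function(e) g * 0)
    if (!all(is.finite(step)) || max(abs(step)) < 1e-10) break
    lam <- 1
    repeat {
      cand <- par - lam * step
      f1 <- obj(cand)
      if (is.finite(f1) && f1 >= f0 - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-8) { cand <- par; f1 <- f0; break }
    }
    moved <- max(abs(cand - par))
    par <- cand; f0 <- f1
    if (moved < 1e-10) break
  }
  a <- clamp(par[1], settings$a_bounds[1], settings$a_bounds[2])
  b <- clamp(-par[2] / a, settings$b_bounds[1], settings$b_bounds[2])
  c(a, b)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @export
print.irt_2pl_fit <- function(x, ...) {
  cat(sprintf("<irt_2pl_fit> %d items, %d persons; logLik %.2f after %d EM iterations%s\n",
              x$n_items, x$n_persons, x$loglik, x$n_iter,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @rdname fit_2pl
#' @param x An `irt_2pl_fit` object.
#' @param ... Unused.
#' @method tidy irt_2pl_fit
#' @export
tidy.irt_2pl_fit <- function(x, ...) {
  tibble::tibble(item = seq_len(x$n_items), a_hat = x$a_hat, b_hat = x$b_hat,
                 converged = x$item_converged)
}

#' @rdname fit_2pl
#' @method glance irt_2pl_fit
#' @export
glance.irt_2pl_fit <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, n_iter = x$n_iter,
                 converged = x$converged,
                 n_persons = x$n_persons, n_items = x$n_items)
}

#' Maximum likelihood ability estimate for one response vector
#'
#' Solves the 2PL score equation `sum_j a_j (u_j - P_j(theta)) = 0`. The
#' score is strictly decreasing in theta, so the interior root is unique and
#' found by bisection-safeguarded root finding on `[-theta_max, theta_max]`.
#' All-correct vectors are clamped to `+theta_max` (`status = "clamped_high"`),
#' all-incorrect to `-theta_max` (`"clamped_low"`).
#'
#' @param u Binary response vector of length J.
#' @param a,b Item parameter vectors.
#' @param theta_max Clamp bound (default 4).
#' @return List with `theta_hat` and `status`
#'   (`"interior"`, `"clamped_low"`, `"clamped_high"`).
#' @export
estimate_theta_mle <- function(u, a, b, theta_max = 4) {
  if (length(u) < 1L) stop("empty response vector", call. = FALSE)
  stopifnot(length(a) == length(u), length(b) == length(u), all(a > 0))
  score <- function(th) sum(a * (u - stats::plogis(a * (th - b))))
  s_lo <- score(-theta_max); s_hi <- score(theta_max)
  if (s_hi >= 0) return(list(theta_hat = theta_max, status = "clamped_high"))
  if (s_lo <= 0) return(list(theta_hat = -theta_max, status = "clamped_low"))
  root <- stats::uniroot(score, c(-theta_max, theta_max), tol = 1e-10)$root
  list(theta_hat = root, status = "interior")
}

#' Maximum likelihood abilities for a response matrix
#'
#' Row-wise [estimate_theta_mle()], vectorized over persons.
#'
#' @param U Binary I x J response matrix.
#' @param items Item parameters: a tibble/data frame with columns `a`/`b` (or
#'   `a_hat`/`b_hat`), or an `irt_2pl_fit`.
#' @param theta_max Clamp bound for perfect / zero scores.
#' @return Tibble with `person`, `theta_hat`, `status`.
#' @export
estimate_abilities <- function(U, items, theta_max = 4) {
  ab <- item_ab(items)
  U <- as.matrix(U)
  stopifnot(ncol(U) == length(ab$a))
  res <- lapply(seq_len(nrow(U)), function(i)
    estimate_theta_mle(U[i, ], ab$a, ab$b, theta_max))
  tibble::tibble(person = seq_len(nrow(U)),
                 theta_hat = vapply(res, `[[`, numeric(1), "theta_hat"),
                 status = vapply(res, `[[`, character(1), "status"))
}

# Accept an ItemBank tibble (a, b), an estimates tibble (a_hat, b_hat), or a fit.
item_ab <- function(items) {
  if (inherits(items, "irt_2pl_fit")) return(list(a = items$a_hat, b = items$b_hat))
  nm <- names(items)
  if (all(c("a", "b") %in% nm)) return(list(a = items$a, b = items$b))
  if (all(c("a_hat", "b_hat") %in% nm)) return(list(a = items$a_hat, b = items$b_hat))
  stop("`items` must provide columns a/b or a_hat/b_hat", call. = FALSE)
}
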