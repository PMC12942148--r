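#' Baseline lz* pipeline on the full sample
#'
#' The conventional workflow: calibrate the 2PL on all respondents by
#' marginal maximum likelihood, estimate each ability by MLE, compute the
#' Snijders-corrected lz*, and flag persons below the critical value as
#' non-effortful. Effortful = not flagged.
#'
#' @param U Binary response matrix (or an `effort_sim`, whose `U` is used).
#' @param critical lz* flagging threshold (default -1.645).
#' @param settings Calibration settings, see [calib_settings()].
#' @return A list of class `"lzstar_baseline"`: per-person tibble `result`
#'   (`person`, `theta_hat`, `status`, `lz`, `lz_star`, `flagged`,
#'   `effortful`), the `fit` (`irt_2pl_fit`), and `critical`.
#' @export
run_baseline_lzstar <- function(U, critical = -1.645,
                                settings = calib_settings()) {
  if (inherits(U, "effort_sim")) U <- U$U
  fit <- fit_2pl(U, settings)
  pf <- person_fit(U, fit, critical = critical)
  # degenerate statistics carry no evidence of aberrance: person retained
  pf$effortful <- !pf$flagged | is.na(pf$flagged)
  structure(list(result = pf, fit = fit, critical = critical),
            class = "lzstar_baseline")
}

#' @export
print.lzstar_baseline <- function(x, ...) {
  cat(sprintf("<lzstar_baseline> %d persons; %d flagged non-effortful at %.3f\n",
              nrow(x$result), sum(x$result$flagged, na.rm = TRUE), x$critical))
  invisible(x)
}

#' @rdname run_baseline_lzstar
#' @param x An `lzstar_baseline` object.
#' @param ... Unused.
#' @method tidy lzstar_baseline
#' @export
tidy.lzstar_baseline <- function(x, ...) x$result

#' The two-step method: cluster-purified calibration, then lz*
#'
#' Step 1 partitions respondents into two groups from their response times
#' (K-means by default) and labels the slower group effortful. Step 2
#' calibrates the 2PL on the step-1 effortful group only, so rapid guesses do
#' not contaminate the item parameter estimates. Step 3 computes ability MLEs
#' and lz* under those cleaner parameters — for all respondents
#' (`variant = "all"`), or only for the respondents the clustering flagged
#' non-effortful (`variant = "flagged_only"`, the computationally lighter
#' version). Step 4 forms the final effortful group: persons whose lz* is not
#' below the critical value, joined (under `flagged_only`) with the entire
#' step-1 effortful cluster.
#'
#' When the step-1 effortful cluster is too small to support calibration
#' (fewer than `max(50, 2 J)` members), the full sample is used instead and
#' the result records the fallback.
#'
#' @param U Binary response matrix, or an `effort_sim` (then `T_mat` may be
#'   omitted).
#' @param T_mat Response-time matrix in seconds.
#' @param variant `"flagged_only"` (default, the recommended efficient
#'   version) or `"all"`.
#' @param method Step-1 clustering: `"kmeans"` (default) or `"som"`.
#' @param feature_kind Step-1 features, see [effort_features()].
#' @param critical lz* threshold (default -1.645).
#' @param seed Seed for the clustering step.
#' @param settings Calibration settings.
#' @return A list of class `"two_step"`: per-person tibble `result`
#'   (`person`, `step1_effortful`, `theta_hat`, `lz_star`, `evaluated`,
#'   `effortful`), `fit` (the step-2 calibration), `variant`,
#'   `calibration_fallback`.
#' @examples
#' sim <- simulate_effort_data(effort_config(I = 400, J = 15, seed = 11))
#' ts <- run_two_step(sim)
#' table(truth = sim$persons$is_noneffortful, pred = !ts$result$effortful)
#' @export
run_two_step <- function(U, T_mat = NULL,
                         variant = c("flagged_only", "all"),
                         method = c("kmeans", "som"),
                         feature_kind = "raw_rt",
                         critical = -1.645, seed = 1L,
                         settings = calib_settings()) {
  variant <- match.arg(variant)
  method <- match.arg(method)
  if (inherits(U, "effort_sim")) {
    if (is.null(T_mat)) T_mat <- U$T_mat
    U <- U$U
  }
  if (is.null(T_mat)) stop("`T_mat` is required", call. = FALSE)
  U <- as.matrix(U); T_mat <- as.matrix(T_mat)
  stopifnot(all(dim(U) == dim(T_mat)))
  I <- nrow(U); J <- ncol(U)

  # Step 1: unsupervised split on response times
  step1 <- cluster_respondents(T_mat, U, method = method,
                               feature_kind = feature_kind, seed = seed)
  step1_eff <- step1$effortful

  # Step 2: calibrate on the effortful cluster only
  min_n <- max(50L, 2L * J)
  fallback <- sum(step1_eff) < min_n
  if (fallback) {
    warning("step-1 effortful cluster has ", sum(step1_eff),
            " members (< ", min_n, "); falling back to full-sample calibration")
    fit <- fit_2pl(U, settings)
  } else {
    fit <- fit_2pl(U[step1_eff, , drop = FALSE], settings)
  }

  # Step 3: lz* under the purified parameters
  eval_idx <- if (variant == "all") seq_len(I) else which(!step1_eff)
  lz_star <- rep(NA_real_, I)
  theta_hat <- rep(NA_real_, I)
  if (length(eval_idx) > 0) {
    pf <- person_fit(U[eval_idx, , drop = FALSE], fit, critical = critical)
    lz_star[eval_idx] <- pf$lz_star
    theta_hat[eval_idx] <- pf$theta_hat
  }

  # Step 4: merge into the final effortful group; a degenerate (undefined)
  # lz* carries no evidence of aberrance, so the person is retained
  passes <- !flag_noneffortful(lz_star, critical)   # lz* >= critical
  passes[is.na(passes) & seq_len(I) %in% eval_idx] <- TRUE
  passes[is.na(passes)] <- FALSE
  effortful <- if (variant == "all") passes else (step1_eff | passes)

  result <- tibble::tibble(
    person = seq_len(I),
    step1_effortful = step1_eff,
    theta_hat = theta_hat,
    lz_star = lz_star,
    evaluated = seq_len(I) %in% eval_idx,
    effortful = effortful
  )
  structure(list(result = result, fit = fit, variant = variant,
                 method = method, critical = critical,
                 calibration_fallback = fallback, step1 = step1),
            class = "two_step")
}

#' @export
print.two_step <- function(x, ...) {
  cat(sprintf(
    "<two_step> variant=%s, step1=%s; %d/%d step-1 effortful, %d final effortful%s\n",
    x$variant, x$method, sum(x$result$step1_effortful), nrow(x$result),
    sum(x$result$effortful),
    if (x$calibration_fallback) " [full-sample calibration fallback]" else ""))
  invisible(x)
}

#' @rdname run_two_step
#' @param x A `two_step` object.
#' @param ... Unused.
#' @method tidy two_step
#' @export
tidy.two_step <- function(x, ...) x$result

#' @rdname run_two_step
#' @method glance two_step
#' @export
glance.two_step <- function(x, ...) {
  tibble::tibble(variant = x$variant, method = x$method,
                 n_step1_effortful = sum(x$result$step1_effortful),
                 n_final_effortful = sum(x$result$effortful),
                 calibration_fallback = x$calibration_fallback,
                 calib_loglik = x$fit$loglik)
}
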