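#' Classification metrics for the effortful class
#'
#' Recall is the proportion of truly effortful respondents that were
#' identified as effortful; precision is the proportion of predicted
#' effortful respondents that truly are; F1 is their harmonic mean. The
#' positive class is *effortful* throughout.
#'
#' @param truth Logical (or 0/1) vector, `TRUE` = truly effortful.
#' @param pred Logical vector, `TRUE` = predicted effortful.
#' @return One-row tibble: `tp`, `fp`, `fn`, `tn`, `recall`, `precision`,
#'   `f1`. Precision (and hence F1) is `NA` when nothing is predicted
#'   effortful.
#' @export
classification_metrics <- function(truth, pred) {
  if (length(truth) != length(pred))
    stop("`truth` and `pred` must have equal length", call. = FALSE)
  truth <- as.logical(truth); pred <- as.logical(pred)
  if (!any(truth)) stop("`truth` contains no effortful person", call. = FALSE)
  tp <- sum(truth & pred); fp <- sum(!truth & pred)
  fn <- sum(truth & !pred); tn <- sum(!truth & !pred)
  recall <- tp / (tp + fn)
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  f1 <- if (is.na(precision) || precision + recall == 0) {
    if (tp == 0) 0 else NA_real_
  } else 2 * precision * recall / (precision + recall)
  tibble::tibble(tp = tp, fp = fp, fn = fn, tn = tn,
                 recall = recall, precision = precision, f1 = f1)
}

#' Item-parameter recovery summary
#'
#' Medians (robust to the occasional extreme calibration outlier) of the
#' absolute errors and squared errors of the discrimination and difficulty
#' estimates, pooled over items and, when several calibrations are supplied,
#' over replications.
#'
#' @param truth Item tibble with columns `a`, `b` (and `item`).
#' @param est Estimates: a tibble with `a_hat`, `b_hat` (and `item`), an
#'   `irt_2pl_fit`, or a list of either (one element per replication).
#' @return One-row tibble: `med_abs_bias_a`, `med_abs_bias_b`, `med_mse_a`,
#'   `med_mse_b`, `n_items`, `n_replications`.
#' @export
parameter_recovery_summary <- function(truth, est) {
  if (!is.data.frame(truth) || !all(c("a", "b") %in% names(truth)))
    stop("`truth` must have columns `a` and `b`", call. = FALSE)
  if (inherits(est, "irt_2pl_fit") || is.data.frame(est)) est <- list(est)
  errs <- purrr::map(est, function(e) {
    if (inherits(e, "irt_2pl_fit")) e <- tidy(e)
    if (!all(c("a_hat", "b_hat") %in% names(e)))
      stop("estimates must have columns `a_hat` and `b_hat`", call. = FALSE)
    if (nrow(e) != nrow(truth))
      stop("estimate/truth item counts differ", call. = FALSE)
    if ("item" %in% names(e) && "item" %in% names(truth)) {
      e <- e[match(truth$item, e$item), ]
      if (anyNA(e$a_hat)) stop("item IDs do not align", call. = FALSE)
    }
    tibble::tibble(ea = e$a_hat - truth$a, eb = e$b_hat - truth$b)
  })
  pooled <- dplyr::bind_rows(errs)
  tibble::tibble(
    med_abs_bias_a = stats::median(abs(pooled$ea)),
    med_abs_bias_b = stats::median(abs(pooled$eb)),
    med_mse_a = stats::median(pooled$ea^2),
    med_mse_b = stats::median(pooled$eb^2),
    n_items = nrow(truth),
    n_replications = length(errs)
  )
}

#' Mean-sigma linking of 2PL estimates onto a reference metric
#'
#' A 2PL calibration is identified only up to an affine transformation of the
#' latent scale: fitting a subsample whose ability distribution is shifted or
#' compressed (e.g. the slow cluster, whose members are low-ability through
#' the speed-ability correlation) returns estimates on that subsample's
#' metric. Before comparing such estimates with reference values the metric
#' must be aligned. Mean-sigma linking matches the mean and standard
#' deviation of the difficulties: `b' = A b + B`, `a' = a / A` with
#' `A = sd(b_ref) / sd(b)` and `B = mean(b_ref) - A mean(b)`.
#'
#' @param est Estimates tibble with `a_hat`, `b_hat` (or an `irt_2pl_fit`).
#' @param ref Reference item tibble with columns `a`, `b` (usually the truth).
#' @return The estimates tibble with `a_hat`, `b_hat` transformed onto the
#'   reference metric (attributes `A`, `B` record the transformation).
#' @export
link_mean_sigma <- function(est, ref) {
  if (inherits(est, "irt_2pl_fit")) est <- tidy(est)
  stopifnot(all(c("a_hat", "b_hat") %in% names(est)),
            all(c("a", "b") %in% names(ref)), nrow(est) == nrow(ref))
  A <- stats::sd(ref$b) / stats::sd(est$b_hat)
  B <- mean(ref$b) - A * mean(est$b_hat)
  out <- est
  out$b_hat <- A * est$b_hat + B
  out$a_hat <- est$a_hat / A
  attr(out, "A") <- A
  attr(out, "B") <- B
  out
}

#' Score a method's effort labels against the simulation truth
#'
#' @param sim An `effort_sim`.
#' @param effortful_pred Logical vector of predicted effortful labels.
#' @return One-row tibble from [classification_metrics()] with truth taken
#'   from the simulation (`TRUE` = effortful person).
#' @export
score_against_truth <- function(sim, effortful_pred) {
  stopifnot(inherits(sim, "effort_sim"))
  classification_metrics(!sim$persons$is_noneffortful, effortful_pred)
}
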