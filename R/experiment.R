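#' Factorial design grid for the Monte-Carlo study
#'
#' Full cross of sample size, test length, non-effort prevalence, severity
#' level and non-effortful speed level. The default levels span 72 cells; the
#' default replication count (20) is a desk-scale budget — set
#' `n_replications = 200` for the full study budget.
#'
#' @param I_levels Sample sizes.
#' @param J_levels Test lengths.
#' @param pi_levels Non-effort prevalences.
#' @param severity_levels `"low"` and/or `"high"`.
#' @param drt_levels `"low"` and/or `"high"` non-effortful speed.
#' @param n_replications Replications per cell.
#' @param base_seed Base seed; per-(cell, replication) seeds are derived
#'   deterministically so any cell reruns in isolation.
#' @return A list of class `"design_grid"` with a `cells` tibble.
#' @export
design_grid <- function(I_levels = c(500L, 1000L, 2000L),
                        J_levels = c(15L, 30L, 50L),
                        pi_levels = c(0.2, 0.4),
                        severity_levels = c("low", "high"),
                        drt_levels = c("low", "high"),
                        n_replications = 20L,
                        base_seed = 1L) {
  lv <- list(I_levels, J_levels, pi_levels, severity_levels, drt_levels)
  if (any(lengths(lv) == 0L)) stop("empty factor level set", call. = FALSE)
  cells <- tidyr::expand_grid(I = as.integer(I_levels),
                              J = as.integer(J_levels),
                              pi = pi_levels,
                              severity = severity_levels,
                              drt = drt_levels)
  cells$cell <- seq_len(nrow(cells))
  structure(list(cells = cells,
                 n_replications = as.integer(n_replications),
                 base_seed = as.integer(base_seed)),
            class = "design_grid")
}

#' Deterministic per-(cell, replication) seed
#'
#' Counter-based derivation: a small multiplicative hash of
#' (base seed, cell index, replication index), kept below 2^31 so it is a
#' valid R integer seed. Distinct counters give distinct streams without any
#' shared-state bookkeeping.
#'
#' @param base_seed,cell,replication Integers.
#' @return An integer seed.
#' @export
derive_seed <- function(base_seed, cell, replication) {
  m <- 2147483647                       # 2^31 - 1
  h <- (as.numeric(base_seed) %% m)
  h <- (h * 1000003 + as.numeric(cell)) %% m
  h <- (h * 1000003 + as.numeric(replication)) %% m
  as.integer(h + 1)
}

#' Expand a design grid into per-replication simulation configs
#'
#' @param grid A [design_grid()].
#' @return Tibble with one row per (cell, replication) holding the cell
#'   factors, `replication`, `seed`, and a `config` list-column of
#'   [effort_config()] objects.
#' @export
expand_design <- function(grid) {
  stopifnot(inherits(grid, "design_grid"))
  plan <- tidyr::expand_grid(cell = grid$cells$cell,
                             replication = seq_len(grid$n_replications)) |>
    dplyr::left_join(grid$cells, by = "cell") |>
    dplyr::mutate(seed = derive_seed(grid$base_seed, .data$cell, .data$replication))
  plan$config <- purrr::pmap(
    plan[, c("I", "J", "pi", "severity", "drt", "seed")],
    function(I, J, pi, severity, drt, seed)
      effort_config(I = I, J = J, pi = pi, severity = severity,
                    drt = drt, seed = seed))
  plan
}

run_one_method <- function(sim, method, critical = -1.645) {
  pred <- switch(
    method,
    lzstar_baseline = run_baseline_lzstar(sim, critical = critical)$result$effortful,
    kmeans = cluster_respondents(sim$T_mat, sim$U, method = "kmeans",
                                 seed = sim$config$seed)$effortful,
    som = cluster_respondents(sim$T_mat, sim$U, method = "som",
                              seed = sim$config$seed)$effortful,
    twostep_all = run_two_step(sim, variant = "all",
                               seed = sim$config$seed, critical = critical)$result$effortful,
    twostep_flagged = run_two_step(sim, variant = "flagged_only",
                                   seed = sim$config$seed, critical = critical)$result$effortful,
    stop("unknown method: ", method, call. = FALSE)
  )
  pred[is.na(pred)] <- TRUE   # degenerate statistics: leave person unflagged
  score_against_truth(sim, pred)
}

#' Run the factorial Monte-Carlo experiment
#'
#' For every cell x replication of the grid: simulate a dataset, run each
#' requested identification method, and score recall, precision and F1 of the
#' effortful class against the generating truth. Failures in a single
#' (cell, replication, method) are captured as an `error` column, never
#' aborting the sweep.
#'
#' @param grid A [design_grid()].
#' @param methods Subset of `c("lzstar_baseline", "kmeans", "som",
#'   "twostep_all", "twostep_flagged")`.
#' @param out_path Optional CSV path; written incrementally per cell.
#' @param critical lz* threshold.
#' @param verbose Print per-cell progress.
#' @return Tibble with one row per (cell, replication, method).
#' @export
run_experiment <- function(grid,
                           methods = c("lzstar_baseline", "kmeans",
                                       "twostep_flagged"),
                           out_path = NULL, critical = -1.645,
                           verbose = interactive()) {
  plan <- expand_design(grid)
  if (!is.null(out_path)) {
    ok <- tryCatch({ file.create(out_path); TRUE }, warning = function(w) FALSE)
    if (!ok) stop("cannot write to ", out_path, call. = FALSE)
  }
  rows <- purrr::pmap(
    list(plan$cell, plan$replication, plan$config),
    function(cell, replication, config) {
      sim <- simulate_effort_data(config)
      purrr::map(methods, function(m) {
        res <- tryCatch(
          dplyr::mutate(suppressWarnings(run_one_method(sim, m, critical)),
                        error = NA_character_),
          error = function(e)
            tibble::tibble(tp = NA_integer_, fp = NA_integer_,
                           fn = NA_integer_, tn = NA_integer_,
                           recall = NA_real_, precision = NA_real_,
                           f1 = NA_real_, error = conditionMessage(e)))
        dplyr::mutate(res, cell = cell, replication = replication,
                      method = m, .before = 1)
      }) |> dplyr::bind_rows()
    })
  out <- dplyr::bind_rows(rows) |>
    dplyr::left_join(plan[, c("cell", "replication", "I", "J", "pi",
                              "severity", "drt", "seed")],
                     by = c("cell", "replication")) |>
    dplyr::relocate("I", "J", "pi", "severity", "drt", "seed",
                    .after = "replication")
  if (verbose)
    message(sprintf("experiment: %d rows (%d cells x %d reps x %d methods)",
                    nrow(out), nrow(grid$cells), grid$n_replications,
                    length(methods)))
  if (!is.null(out_path)) readr::write_csv(out, out_path)
  out
}

#' Read a response / response-time dataset from CSV
#'
#' Both files must carry a `person` ID column and item IDs in the header.
#' Rows and item columns of the times file are realigned to the responses
#' file by their IDs.
#'
#' @param responses_path CSV of binary responses.
#' @param times_path CSV of positive response times (seconds).
#' @return List with matrices `U` and `T_mat` (persons as rownames, item IDs
#'   as colnames).
#' @export
read_effort_data <- function(responses_path, times_path) {
  rd <- readr::read_csv(responses_path, show_col_types = FALSE)
  td <- readr::read_csv(times_path, show_col_types = FALSE)
  if (!"person" %in% names(rd) || !"person" %in% names(td))
    stop("both files need a `person` ID column", call. = FALSE)
  items <- setdiff(names(rd), "person")
  miss <- setdiff(items, names(td))
  if (length(miss) > 0)
    stop("times file is missing item column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!setequal(rd$person, td$person))
    stop("person IDs differ between the two files", call. = FALSE)
  td <- td[match(rd$person, td$person), c("person", items)]

  U <- as.matrix(rd[items])
  bad <- which(!(U %in% c(0, 1)))
  if (length(bad) > 0) {
    rc <- arrayInd(bad[1], dim(U))
    stop(sprintf("non-binary response at person %s, item %s (value %s)",
                 rd$person[rc[1]], items[rc[2]], U[bad[1]]), call. = FALSE)
  }
  T_mat <- as.matrix(td[items])
  badt <- which(!(T_mat > 0))
  if (length(badt) > 0) {
    rc <- arrayInd(badt[1], dim(T_mat))
    stop(sprintf("non-positive time at person %s, item %s (value %s)",
                 td$person[rc[1]], items[rc[2]], T_mat[badt[1]]), call. = FALSE)
  }
  storage.mode(U) <- "integer"
  rownames(U) <- rownames(T_mat) <- rd$person
  list(U = U, T_mat = T_mat)
}

#' Summarize an experiment table per cell and method
#'
#' @param results Tibble from [run_experiment()].
#' @return Tibble of per-(cell, method) means of recall, precision and F1
#'   over replications (NA rows dropped).
#' @export
summarize_experiment <- function(results) {
  results |>
    dplyr::filter(is.na(.data$error)) |>
    dplyr::group_by(.data$cell, .data$I, .data$J, .data$pi, .data$severity,
                    .data$drt, .data$method) |>
    dplyr::summarise(
      n_reps = dplyr::n(),
      recall = mean(.data$recall, na.rm = TRUE),
      precision = mean(.data$precision, na.rm = TRUE),
      f1 = mean(.data$f1, na.rm = TRUE),
      .groups = "drop")
}
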