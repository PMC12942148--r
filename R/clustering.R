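#' Build the respondent feature matrix for clustering
#'
#' The first identification step clusters respondents on their response
#' times. Rapid guesses take well under a second while effortful answers take
#' tens of seconds, so raw per-item seconds separate the two behaviors by
#' sheer magnitude.
#'
#' @param T_mat Positive I x J response-time matrix in seconds.
#' @param U Optional binary response matrix (needed for the accuracy variant).
#' @param feature_kind `"raw_rt"` (per-item seconds, the default), `"log_rt"`
#'   (per-item log-seconds), or `"log_rt_plus_accuracy"` (log-seconds plus the
#'   binary responses as extra columns).
#' @return Numeric matrix, persons x features.
#' @export
effort_features <- function(T_mat, U = NULL,
                            feature_kind = c("raw_rt", "log_rt",
                                             "log_rt_plus_accuracy")) {
  feature_kind <- match.arg(feature_kind)
  T_mat <- as.matrix(T_mat)
  if (any(T_mat <= 0)) stop("response times must be positive", call. = FALSE)
  X <- switch(feature_kind,
              raw_rt = T_mat,
              log_rt = log(T_mat),
              log_rt_plus_accuracy = {
                if (is.null(U)) stop("`U` required for accuracy features", call. = FALSE)
                cbind(log(T_mat), as.matrix(U))
              })
  unname(X)
}

#' Two-group K-means partition of respondents
#'
#' Lloyd iterations with Euclidean distance, run to convergence from
#' `n_restarts` random center draws; the best solution by total
#' within-cluster sum of squares is returned. Deterministic given `seed`.
#'
#' @param X Numeric feature matrix (persons x features), e.g. from
#'   [effort_features()].
#' @param K Number of clusters (2 for the effortful / non-effortful split).
#' @param n_restarts Random restarts.
#' @param seed Integer seed.
#' @return A list of class `"effort_clusters"`: `labels` (integer per
#'   person), `centers`, `tot_withinss`, `method = "kmeans"`.
#' @export
kmeans_partition <- function(X, K = 2L, n_restarts = 5L, seed = 1L) {
  X <- as.matrix(X)
  if (K >= nrow(X)) stop("`K` must be smaller than the number of rows", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  km <- NULL
  for (attempt in 1:20) {
    km <- tryCatch(
      stats::kmeans(X, centers = K, nstart = n_restarts,
                    algorithm = "Lloyd", iter.max = 200L),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(km)) break
  }
  if (is.null(km))  # pathological input; fall back to default algorithm
    km <- stats::kmeans(X, centers = K, nstart = n_restarts, iter.max = 200L)
  structure(list(labels = unname(km$cluster), centers = unname(km$centers),
                 tot_withinss = km$tot.withinss, method = "kmeans"),
            class = "effort_clusters")
}

#' Self-organizing map configuration
#'
#' @param grid_dim Map dimensions (rows, cols); default 4 x 4.
#' @param topology `"hexagonal"` or `"rectangular"` node lattice.
#' @param epochs Passes over the data during online training.
#' @param lr Initial and final learning rate; decays linearly.
#' @param radius Initial neighborhood radius (default: half the grid
#'   diagonal); decays linearly to zero over training.
#' @param seed Integer seed for initialization and presentation order.
#' @return A list of class `"som_config"`.
#' @export
som_config <- function(grid_dim = c(4L, 4L),
                       topology = c("hexagonal", "rectangular"),
                       epochs = 100L, lr = c(0.05, 0.01),
                       radius = NULL, seed = 1L) {
  topology <- match.arg(topology)
  stopifnot(length(grid_dim) == 2L, prod(grid_dim) >= 2L, epochs >= 1L)
  structure(list(grid_dim = as.integer(grid_dim), topology = topology,
                 epochs = as.integer(epochs), lr = lr,
                 radius = radius, seed = as.integer(seed)),
            class = "som_config")
}

som_node_coords <- function(grid_dim, topology) {
  g <- expand.grid(row = seq_len(grid_dim[1]), col = seq_len(grid_dim[2]))
  x <- g$col; y <- g$row
  if (topology == "hexagonal") {
    x <- x + ifelse(g$row %% 2 == 0, 0.5, 0)   # offset even rows
    y <- y * sqrt(3) / 2
  }
  cbind(x, y)
}

#' Two-group partition by a self-organizing map
#'
#' Online SOM training: codebook vectors start at small perturbations of the
#' data mean; for each presented observation the best matching unit (BMU, the
#' nearest codebook by Euclidean distance) and its lattice neighbors within
#' the current radius move toward the observation, with learning rate and
#' radius decaying linearly (the radius to zero) over training. The trained
#' codebook is then bisected by 2-means and each person inherits the section
#' of its BMU.
#'
#' @param X Numeric feature matrix (persons x features).
#' @param config A [som_config()].
#' @return `"effort_clusters"` list: `labels` (section 1/2 per person),
#'   `centers` (the two section centroids in feature space), `codebook`,
#'   `bmu` (node index per person), `quantization_error`, `method = "som"`.
#' @export
som_partition <- function(X, config = som_config()) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  n_nodes <- prod(config$grid_dim)
  if (n < n_nodes) stop("fewer observations than SOM nodes", call. = FALSE)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  coords <- som_node_coords(config$grid_dim, config$topology)
  r0 <- if (is.null(config$radius))
    sqrt(sum((apply(coords, 2, max) - apply(coords, 2, min))^2)) / 2
  else config$radius

  ctr <- colMeans(X)
  sdv <- pmax(apply(X, 2, stats::sd), 1e-8)
  W <- matrix(rep(ctr, each = n_nodes), n_nodes, d) +
    matrix(stats::rnorm(n_nodes * d), n_nodes, d) *
    matrix(rep(sdv * 0.05, each = n_nodes), n_nodes, d)

  total_steps <- config$epochs * n
  step <- 0L
  for (ep in seq_len(config$epochs)) {
    for (i in sample.int(n)) {
      step <- step + 1L
      frac <- step / total_steps
      lr_t <- config$lr[1] + (config$lr[2] - config$lr[1]) * frac
      rad_t <- r0 * (1 - frac)
      xi <- X[i, ]
      dists2 <- rowSums(sweep(W, 2L, xi)^2)
      bmu <- which.min(dists2)
      latdist <- sqrt(rowSums(sweep(coords, 2L, coords[bmu, ])^2))
      nb <- latdist <= max(rad_t, 0)
      if (rad_t > 0) {
        h <- exp(-(latdist[nb]^2) / (2 * max(rad_t, 1e-8)^2))
      } else h <- 1  # radius exhausted: BMU-only updates
      W[nb, ] <- W[nb, , drop = FALSE] +
        lr_t * h * (matrix(xi, sum(nb), d, byrow = TRUE) - W[nb, , drop = FALSE])
    }
  }

  bmu_of <- function(M) {
    # nearest codebook per row of M
    cross <- M %*% t(W)
    d2 <- outer(rowSums(M^2), rowSums(W^2), "+") - 2 * cross
    max.col(-d2, ties.method = "first")
  }
  bmu <- bmu_of(X)
  qe <- mean(sqrt(rowSums((X - W[bmu, , drop = FALSE])^2)))

  occupied <- sort(unique(bmu))
  if (length(occupied) < 2L)
    stop("SOM collapsed to a single occupied node; cannot split", call. = FALSE)
  split <- stats::kmeans(W, centers = 2L, nstart = 5L, iter.max = 100L)
  labels <- split$cluster[bmu]
  if (length(unique(labels)) < 2L) {
    # bisect only the occupied codebooks instead
    split2 <- stats::kmeans(W[occupied, , drop = FALSE], centers = 2L,
                            nstart = 5L, iter.max = 100L)
    sec <- integer(n_nodes); sec[occupied] <- split2$cluster
    labels <- sec[bmu]
  }
  centers <- rbind(colMeans(X[labels == 1L, , drop = FALSE]),
                   colMeans(X[labels == 2L, , drop = FALSE]))
  structure(list(labels = unname(labels), centers = centers, codebook = W,
                 bmu = bmu, quantization_error = qe, method = "som"),
            class = "effort_clusters")
}

#' Label clusters as effortful / non-effortful by mean response time
#'
#' Rapid guessing is fast, so the group spending more time per response is
#' taken as the effortful one. Ties go to the lower cluster index.
#'
#' @param labels Integer cluster labels (exactly two occupied groups).
#' @param T_mat Response-time matrix aligned with `labels`.
#' @return A list of class `"effort_partition"`: `effortful` (logical per
#'   person), `effortful_cluster`, `mean_rt` (named per-cluster means),
#'   `labels`.
#' @export
label_clusters_by_rt <- function(labels, T_mat) {
  T_mat <- as.matrix(T_mat)
  stopifnot(length(labels) == nrow(T_mat))
  grp <- sort(unique(labels))
  if (length(grp) != 2L)
    stop("expected exactly 2 occupied clusters, got ", length(grp), call. = FALSE)
  mean_rt <- vapply(grp, function(g) mean(T_mat[labels == g, ]), numeric(1))
  names(mean_rt) <- grp
  eff <- grp[which.max(mean_rt)]  # which.max takes the first (lower index) on ties
  structure(list(effortful = labels == eff, effortful_cluster = eff,
                 mean_rt = mean_rt, labels = labels),
            class = "effort_partition")
}

#' Cluster respondents on response times and label the groups
#'
#' Convenience wrapper: builds the feature matrix, partitions with K-means or
#' a SOM, and labels the slower cluster effortful.
#'
#' @param T_mat Response-time matrix (seconds).
#' @param U Optional response matrix for accuracy-augmented features.
#' @param method `"kmeans"` or `"som"`.
#' @param feature_kind Passed to [effort_features()].
#' @param seed Integer seed.
#' @param ... Further arguments to [kmeans_partition()] or, for SOM, a
#'   `config = som_config()`.
#' @return Tibble with `person`, `cluster`, `effortful`; the partition object
#'   is attached as attribute `"partition"`.
#' @export
cluster_respondents <- function(T_mat, U = NULL,
                                method = c("kmeans", "som"),
                                feature_kind = "raw_rt", seed = 1L, ...) {
  method <- match.arg(method)
  X <- effort_features(T_mat, U, feature_kind)
  cl <- if (method == "kmeans") {
    kmeans_partition(X, K = 2L, seed = seed, ...)
  } else {
    dots <- list(...)
    cfg <- dots$config %||% som_config(seed = seed)
    som_partition(X, cfg)
  }
  part <- label_clusters_by_rt(cl$labels, T_mat)
  out <- tibble::tibble(person = seq_len(nrow(as.matrix(T_mat))),
                        cluster = cl$labels, effortful = part$effortful)
  attr(out, "partition") <- part
  attr(out, "clusters") <- cl
  out
}
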