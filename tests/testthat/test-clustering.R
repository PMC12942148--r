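two_cloud_data <- function(n1 = 60, n2 = 40, d = 3, gap = 20, seed = 61) {
  set.seed(seed)
  rbind(matrix(rnorm(n1 * d, 0, 0.5), n1, d),
        matrix(rnorm(n2 * d, gap, 0.5), n2, d))
}

test_that("K-means finds well-separated clouds exactly", {
  X <- matrix(c(0, 0.1, 0.2, 10, 10.1), ncol = 1)
  cl <- kmeans_partition(X, K = 2, seed = 1)
  expect_equal(length(unique(cl$labels[1:3])), 1)
  expect_equal(length(unique(cl$labels[4:5])), 1)
  expect_true(cl$labels[1] != cl$labels[4])
  expect_equal(sort(as.numeric(cl$centers)), c(0.1, 10.05))
})

test_that("more restarts never worsen the K-means objective", {
  set.seed(62)
  X <- matrix(rnorm(300), 100, 3)
  w1 <- kmeans_partition(X, K = 2, n_restarts = 1, seed = 5)$tot_withinss
  w10 <- kmeans_partition(X, K = 2, n_restarts = 10, seed = 5)$tot_withinss
  expect_lte(w10, w1 + 1e-9)
  expect_error(kmeans_partition(X[1:2, ], K = 2), "smaller")
})

test_that("cluster labeling follows mean response time with a fixed tie-break", {
  labels <- c(1, 1, 2, 2)
  T_mat <- matrix(c(33, 33, 0.4, 0.4, 33, 33, 0.4, 0.4), 4, 2)
  part <- label_clusters_by_rt(labels, T_mat)
  expect_equal(part$effortful_cluster, 1)
  expect_equal(part$effortful, c(TRUE, TRUE, FALSE, FALSE))

  # exact tie goes to the lower cluster index
  tie <- label_clusters_by_rt(c(1, 2), matrix(c(5, 5), 2, 1))
  expect_equal(tie$effortful_cluster, 1)

  # invariance to relabeling
  part2 <- label_clusters_by_rt(c(2, 2, 1, 1), T_mat)
  expect_equal(part2$effortful, part$effortful)

  expect_error(label_clusters_by_rt(c(1, 1), matrix(1:4, 2, 2)), "2 occupied")
})

test_that("SOM training reduces quantization error and matches K-means on separated clouds", {
  X <- two_cloud_data()
  cfg <- som_config(grid_dim = c(3, 3), epochs = 30, seed = 9)
  som <- som_partition(X, cfg)
  # initial codebooks sit at small perturbations of the data mean
  qe_init <- mean(sqrt(rowSums(sweep(X, 2, colMeans(X))^2)))
  expect_lt(som$quantization_error, qe_init)

  km <- kmeans_partition(X, K = 2, seed = 9)
  agree <- mean((som$labels == som$labels[1]) == (km$labels == km$labels[1]))
  expect_equal(agree, 1)

  # a point equal to a codebook vector maps to that node
  W <- som$codebook
  d2 <- rowSums(sweep(W, 2, W[5, ])^2)
  expect_equal(which.min(d2), 5L)
})

test_that("feature construction validates its inputs", {
  T_mat <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_equal(effort_features(T_mat, feature_kind = "log_rt"), log(T_mat),
               ignore_attr = TRUE)
  expect_error(effort_features(T_mat * -1), "positive")
  expect_error(effort_features(T_mat, feature_kind = "log_rt_plus_accuracy"),
               "required")
  U <- matrix(c(0, 1, 1, 0), 2, 2)
  X <- effort_features(T_mat, U, "log_rt_plus_accuracy")
  expect_equal(dim(X), c(2, 4))
})

test_that("respondent clustering labels the slow group effortful on simulated data", {
  sim <- simulate_effort_data(effort_config(I = 400, J = 15, seed = 63))
  cl <- cluster_respondents(sim$T_mat, sim$U, seed = 1)
  expect_s3_class(cl, "tbl_df")
  expect_equal(nrow(cl), 400)
  part <- attr(cl, "partition")
  expect_equal(max(part$mean_rt), part$mean_rt[as.character(part$effortful_cluster)],
               ignore_attr = TRUE)
  # effortful-labeled persons are slower on average
  expect_gt(mean(sim$T_mat[cl$effortful, ]), mean(sim$T_mat[!cl$effortful, ]))
})
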