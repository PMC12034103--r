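blobs <- function(centers, n_each = 20, sd = 0.3, seed = 0) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k)
    sweep(matrix(rnorm(n_each * ncol(centers), sd = sd), n_each), 2,
          centers[k, ], `+`)))
  rownames(X) <- paste0("p", seq_len(nrow(X)))
  attr(X, "truth") <- rep(seq_len(nrow(centers)), each = n_each)
  X
}

test_that("SMCR is the singleton-cluster fraction", {
  expect_equal(smcr(c(rep(1:8, each = 2), 9, 10)), 0.2)  # 10 clusters, 2 singletons
  expect_equal(smcr(rep(1:3, each = 4)), 0)
  expect_equal(smcr(1:7), 1)
  expect_error(smcr(integer(0)), "empty")
})

test_that("seeded K-means is deterministic and recovers constructed blobs", {
  X <- blobs(matrix(c(0, 0, 10, 0, 0, 10), 3, 2, byrow = TRUE), seed = 1)
  expect_identical(kmeans_cluster(X, 3, seed = 0),
                   kmeans_cluster(X, 3, seed = 0))
  cl <- kmeans_cluster(X, 3, seed = 0)
  expect_equal(compare_clusterings(cl, setNames(attr(X, "truth"),
                                                rownames(X)))$ari, 1)
  two <- matrix(c(0, 0, 5, 5), 2, 2, byrow = TRUE,
                dimnames = list(c("a", "b"), NULL))
  expect_setequal(unname(kmeans_cluster(two, 2)), 1:2)
  expect_error(kmeans_cluster(two, 3), "exceeds")
})

test_that("select_k picks K = 3 on three separated blobs and respects SMCR", {
  X <- blobs(matrix(c(0, 0, 10, 0, 0, 10), 3, 2, byrow = TRUE), seed = 0)
  sel <- select_k(X, k_grid = 2:6, seed = 0)
  expect_equal(sel$chosen_k, 3)
  expect_true(sel$constraint_met)
  expect_lt(sel$report$smcr[sel$report$k == 3], 0.05)
  expect_true(all(sel$report$silhouette >= -1 & sel$report$silhouette <= 1))
  expect_true(all(sel$report$dbi >= 0))
})

test_that("silhouette and DBI orderings match independent recomputation", {
  X <- blobs(matrix(c(0, 0), 1, 2), n_each = 30, seed = 2)  # a single blob
  sel <- select_k(X, k_grid = c(2, 3), seed = 0)
  # oracle: recompute both metrics from their definitions
  d <- as.matrix(dist(X))
  for (K in c(2, 3)) {
    cl <- kmeans_cluster(X, K, seed = 0)
    sil_hand <- mean(vapply(seq_len(nrow(X)), function(i) {
      own <- which(cl == cl[i]); own <- setdiff(own, i)
      a <- mean(d[i, own])
      b <- min(vapply(setdiff(unique(cl), cl[i]),
                      function(c2) mean(d[i, cl == c2]), numeric(1)))
      (b - a) / max(a, b)
    }, numeric(1)))
    expect_equal(sel$report$silhouette[sel$report$k == K], sil_hand,
                 tolerance = 1e-10)
    cent <- t(sapply(sort(unique(cl)), function(c2)
      colMeans(X[cl == c2, , drop = FALSE])))
    s <- sapply(sort(unique(cl)), function(c2)
      mean(sqrt(rowSums(sweep(X[cl == c2, , drop = FALSE], 2,
                              cent[c2, ])^2))))
    dbi_hand <- mean(sapply(seq_len(K), function(i2)
      max(sapply(setdiff(seq_len(K), i2), function(j2)
        (s[i2] + s[j2]) / sqrt(sum((cent[i2, ] - cent[j2, ])^2))))))
    expect_equal(sel$report$dbi[sel$report$k == K], dbi_hand, tolerance = 1e-10)
  }
})

test_that("an all-singleton grid triggers the flagged min-SMCR fallback", {
  X <- blobs(matrix(c(0, 0), 1, 2), n_each = 8, seed = 3)
  sel <- select_k(X, k_grid = 7L, seed = 0)
  expect_false(sel$constraint_met)
  expect_equal(sel$chosen_k, 7L)
})

test_that("subclustering refines clusters and honors the distance threshold", {
  # one K-means cluster that secretly contains two far blobs
  X <- rbind(blobs(matrix(c(0, 0), 1, 2), n_each = 10, sd = 0.2, seed = 4),
             blobs(matrix(c(20, 0), 1, 2), n_each = 10, sd = 0.2, seed = 5))
  rownames(X) <- paste0("q", 1:20)
  assign <- rep(1L, 20)
  sc <- subcluster(X, assign, distance_threshold = 5)
  expect_equal(length(unique(sc$subcluster)), 2L)
  # threshold -> Inf collapses subclusters back onto clusters
  sc_inf <- subcluster(X, assign, distance_threshold = 1e9)
  expect_equal(length(unique(sc_inf$subcluster)), 1L)
  # identical points stay together
  same <- matrix(1, 5, 2, dimnames = list(paste0("r", 1:5), NULL))
  expect_equal(length(unique(subcluster(same, rep(1L, 5),
                                        distance_threshold = 6)$subcluster)), 1L)
  # refinement: subclusters never merge across K-means clusters
  X2 <- blobs(matrix(c(0, 0, 8, 8), 2, 2, byrow = TRUE), n_each = 10, seed = 6)
  cl2 <- kmeans_cluster(X2, 2, seed = 0)
  sc2 <- subcluster(X2, cl2, distance_threshold = 3)
  tab <- table(sc2$subcluster, sc2$cluster)
  expect_true(all(rowSums(tab > 0) == 1))
})

test_that("ARI matches a brute-force pair-counting oracle", {
  a <- c(1, 1, 1, 2, 2, 3, 3, 3)
  b <- c(2, 2, 1, 1, 1, 3, 3, 2)
  pairs_agree <- function(x, y) {
    n <- length(x); s11 <- s00 <- s10 <- s01 <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      sx <- x[i] == x[j]; sy <- y[i] == y[j]
      if (sx && sy) s11 <- s11 + 1
      else if (!sx && !sy) s00 <- s00 + 1
      else if (sx) s10 <- s10 + 1 else s01 <- s01 + 1
    }
    tot <- choose(n, 2)
    ri_exp <- ((s11 + s10) * (s11 + s01) + (s01 + s00) * (s10 + s00)) / tot
    ((s11 + s00) - ri_exp) / (tot - ri_exp)
  }
  expect_equal(compare_clusterings(a, b)$ari, pairs_agree(a, b))
  expect_equal(compare_clusterings(a, a)$ari, 1)
  relab <- c(7, 7, 7, 9, 9, 4, 4, 4)  # renamed labels, same partition
  expect_equal(compare_clusterings(a, relab)$ari, 1)
  expect_equal(compare_clusterings(a, relab)$ami, 1)
})

test_that("AMI matches the reference value on a fixed contingency", {
  a <- c(1, 1, 1, 2, 2, 2, 3, 3, 1, 2)
  b <- c(1, 1, 2, 2, 2, 3, 3, 3, 1, 1)
  # frozen from scikit-learn adjusted_mutual_info_score on this fixture
  expect_equal(adjusted_mutual_information(a, b), 0.20426243363080304,
               tolerance = 1e-10)
})

test_that("clustering comparisons require matching item sets", {
  expect_error(compare_clusterings(setNames(1:3, c("a", "b", "c")),
                                   setNames(1:3, c("a", "b", "d"))),
               "different item sets")
})
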