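# random symmetric dissimilarity matrix with zero diagonal
rand_D <- function(n, seed) {
  set.seed(seed)
  P <- matrix(runif(n * 2), n, 2)
  as.matrix(dist(P))
}

test_that("k = n puts every point in its own cluster with zero inertia", {
  D <- rand_D(6, 1)
  m <- k_medoids(D, k = 6, seed = 3)
  expect_equal(sort(m$medoid_ids), 1:6)
  expect_equal(m$inertia, 0)
  expect_equal(m$n_members, rep(1L, 6))
})

test_that("k_medoids brackets between best-assignment and global optimum", {
  for (seed in 1:8) {
    n <- sample(8:12, 1)
    k <- sample(2:3, 1)
    D <- rand_D(n, 100 + seed)
    m <- k_medoids(D, k = k, seed = seed)
    # <= brute-force best assignment for the returned medoid set
    expect_lte(m$inertia, oracle_inertia_for_medoids(D, m$medoid_ids) + 1e-9)
    # >= global optimum over all medoid k-subsets
    expect_gte(m$inertia, oracle_kmedoids_global(D, k) - 1e-9)
  }
})

test_that("inertia decreases strictly across accepted rounds", {
  for (seed in 1:6) {
    D <- rand_D(30, 200 + seed)
    m <- k_medoids(D, k = 4, seed = seed)
    expect_true(all(diff(m$inertia_trace) < 0))
    expect_equal(m$inertia, tail(m$inertia_trace, 1))
  }
})

test_that("medoids are members of their own clusters and counts sum to n", {
  D <- rand_D(25, 9)
  m <- k_medoids(D, k = 5, seed = 2)
  expect_equal(m$assignment[m$medoid_ids], seq_len(5))
  expect_equal(sum(m$n_members), 25L)
  expect_error(k_medoids(D, k = 26), "at least k")
})

test_that("best_clustering returns the minimal restart and is deterministic", {
  D <- rand_D(40, 12)
  best <- best_clustering(D, k = 4, restarts = 10, seed = 5)
  expect_equal(best$inertia, min(best$restart_inertias))
  expect_true(all(best$inertia <= best$restart_inertias))
  # restarts = 1 equals a single run with the same derived draw
  one <- best_clustering(D, k = 4, restarts = 1, seed = 5)
  single <- k_medoids(D, k = 4, seed = derive_seed(5, 1))
  expect_equal(one$inertia, single$inertia)
  expect_equal(one$medoid_ids, single$medoid_ids)
  again <- best_clustering(D, k = 4, restarts = 10, seed = 5)
  expect_identical(best$medoid_ids, again$medoid_ids)
})

test_that("more restarts never increase the best inertia", {
  D <- rand_D(35, 77)
  inertias <- vapply(c(1, 3, 6, 12), function(r)
    best_clustering(D, k = 5, restarts = r, seed = 7)$inertia, 0)
  expect_true(all(diff(inertias) <= 1e-12))
})

test_that("planted well-separated groups are recovered exactly", {
  skip_if_not_installed("mclust")
  set.seed(55)
  centers <- matrix(c(0, 0, 10, 0, 0, 10), 3, 2, byrow = TRUE)
  labels <- rep(1:3, each = 10)
  P <- centers[labels, ] + matrix(rnorm(60, sd = 0.05), 30, 2)
  D <- as.matrix(dist(P))
  m <- best_clustering(D, k = 3, restarts = 5, seed = 1)
  ari <- mclust::adjustedRandIndex(m$assignment, labels)
  expect_gte(ari, 0.999)
})

test_that("cluster summaries aggregate members correctly", {
  D <- rand_D(20, 3)
  m <- k_medoids(D, k = 3, seed = 4)
  coll <- rep(c(TRUE, FALSE), 10)
  score <- 1:20
  sm <- cluster_summaries(m, collision = coll, ore_score = score)
  expect_equal(sum(sm$n_members), 20L)
  for (c in 1:3) {
    mem <- which(m$assignment == c)
    expect_equal(sm$collision_rate[c], mean(coll[mem]))
    expect_equal(sm$ore_score_mean[c], mean(score[mem]))
  }
})

test_that("membership features arrange zone blocks in ascending zone order", {
  drives <- c("a", "b", "c")
  D1 <- rand_D(3, 1); dimnames(D1) <- list(drives, drives)
  D2 <- rand_D(2, 2); dimnames(D2) <- list(c("a", "c"), c("a", "c"))
  zf <- list(
    z9 = zone_membership_block(D1, c(1L, 2L), drives),
    z2 = zone_membership_block(D2, c(2L, 1L), c("a", "c")))
  X <- membership_features(drives, zf)
  expect_equal(dim(X), c(3L, 4L))
  expect_equal(colnames(X), c("z2_m1", "z2_m2", "z9_m1", "z9_m2"))
  # drive b never visited zone 2 -> NA block
  expect_true(all(is.na(X["b", c("z2_m1", "z2_m2")])))
  # a medoid drive has zero dissimilarity to itself
  expect_equal(X["a", "z9_m1"], 0)
  expect_equal(X["c", "z2_m1"], 0)
  # entries are the dissimilarities to the medoids
  expect_equal(X["b", "z9_m2"], D1["b", "b"] * 0 + D1["b", 2])
})

test_that("drives visiting no zone are dropped with a warning", {
  D1 <- rand_D(2, 5); dimnames(D1) <- list(c("a", "b"), c("a", "b"))
  zf <- list(z1 = zone_membership_block(D1, 1L, c("a", "b")))
  expect_warning(X <- membership_features(c("a", "b", "ghost"), zf),
                 "visited no zone")
  expect_equal(rownames(X), c("a", "b"))
})
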