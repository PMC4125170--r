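test_that("standardization has the documented closed forms and round-trips", {
  d <- data.frame(a = c(1, 2, 3), b = c(10, 30, 20))
  st <- standardize_cohort(d, c("a", "b"))
  expect_equal(unname(st$x[, "a"]), c(-1, 0, 1))
  expect_lt(max(abs(colMeans(st$x))), 1e-10)
  expect_lt(max(abs(apply(st$x, 2, sd) - 1)), 1e-10)

  # location invariance
  d2 <- d; d2$a <- d$a + 100
  st2 <- standardize_cohort(d2, "a")
  expect_equal(unname(st2$x[, "a"]), unname(st$x[, "a"]))

  back <- destandardize(st$x, st$params)
  expect_equal(unname(back), unname(as.matrix(d)), tolerance = 1e-10)

  d$c <- 5
  expect_error(standardize_cohort(d, "c"), "zero variance.*c")
})

test_that("k-means separates well-separated blobs and hits the R2 extremes", {
  set.seed(8)
  x <- rbind(matrix(stats::rnorm(80, -10, 0.1), ncol = 2),
             matrix(stats::rnorm(80, 10, 0.1), ncol = 2))
  truth <- rep(1:2, each = 40)
  fit <- kmeans_partition(x, 2, seed = 1)
  expect_gt(fit$r_squared, 0.99)
  expect_equal(length(unique(paste(fit$assignments, truth))), 2)

  xs <- matrix(c(1, 2, 5, 9), ncol = 1)
  fit_n <- kmeans_partition(xs, 4, seed = 1)
  expect_equal(fit_n$r_squared, 1)
  expect_error(kmeans_partition(xs, 5, seed = 1), "distinct")
  expect_error(kmeans_partition(xs, 1, seed = 1), "k must be")
})

test_that("final centroids are member means and assignments are stable", {
  set.seed(10)
  x <- matrix(stats::rnorm(300), ncol = 3)
  fit <- kmeans_partition(x, 3, seed = 2)
  for (k in 1:3)
    expect_equal(unname(fit$centroids[k, ]),
                 unname(colMeans(x[fit$assignments == k, , drop = FALSE])),
                 tolerance = 1e-8)
  # re-assigning every point to its nearest centroid changes nothing
  d2 <- sapply(1:3, function(j) rowSums(sweep(x, 2, fit$centroids[j, ], "-")^2))
  expect_equal(max.col(-d2, ties.method = "first"), unname(fit$assignments))
  # SS decomposition
  expect_equal(fit$ss_total,
               fit$ss_within + sum((fit$centroids[fit$assignments, ] -
                                      rep(colMeans(x), each = nrow(x)))^2),
               tolerance = 1e-8)
})

test_that("nested refinement makes R2 non-decreasing in k", {
  set.seed(11)
  for (rep in 1:20) {
    x <- matrix(stats::rnorm(60 * 3), ncol = 3)
    prev <- kmeans_partition(x, 2, seed = rep)
    for (k in 3:5) {
      fit <- kmeans_partition(x, k, seed = rep, init = "nested", previous = prev)
      expect_gte(fit$r_squared, prev$r_squared - 1e-12)
      prev <- fit
    }
  }
})

test_that("CCC exceeds 10 on clean clusters and stays low on uniform noise", {
  set.seed(12)
  ctr <- matrix(stats::rnorm(15, sd = 8), 3, 5)
  cl <- sample(1:3, 300, replace = TRUE)
  x <- ctr[cl, ] + matrix(stats::rnorm(300 * 5, sd = 0.4), 300, 5)
  expect_gt(cubic_clustering_criterion(x, cl), 10)
  expect_equal(cubic_clustering_criterion(x, cl),
               cubic_clustering_criterion(x, cl))  # deterministic

  vals <- replicate(25, {
    xx <- matrix(stats::runif(150 * 3), 150, 3)
    km <- kmeans_partition(xx, sample(2:5, 1), seed = sample.int(1e6, 1))
    cubic_clustering_criterion(xx, km$assignments)
  })
  expect_lt(mean(vals), 2)
  expect_error(cubic_clustering_criterion(x, rep(1, 300)), "single cluster")
})

test_that("choose_k applies the CCC/R2-increment rule with its fallback", {
  d <- data.frame(k = 2:4, r_squared = c(0.3, 0.5, 0.55), ccc = c(5, 14, 12))
  expect_equal(choose_k(d), 3)
  d2 <- data.frame(k = 2:4, r_squared = c(0.3, 0.5, 0.55), ccc = c(9, 8, 7))
  expect_warning(kk <- choose_k(d2), "CCC")
  expect_equal(kk, 2)
  expect_error(choose_k(d[0, ]), "empty")
})

test_that("cluster_cohort relabels by size and projects consistently", {
  co <- generate_cohort(small_spec(1200, seed = 55))
  cm <- cluster_cohort(co, k = 3, seed = 55)
  sizes <- table(cm$assignments)
  expect_true(all(diff(as.integer(sizes)) <= 0))
  expect_equal(sort(unique(cm$assignments)), 1:3)
  # a subject sitting exactly on a centroid is assigned to that cluster
  cent_orig <- destandardize(cm$centroids, cm$params)
  fake <- as.data.frame(cent_orig)
  names(fake) <- cm$variables
  expect_equal(assign_cluster(cm, fake), 1:3)
  # projection of training data reproduces training assignments
  expect_equal(assign_cluster(cm, co), unname(cm$assignments))
})
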