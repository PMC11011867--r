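test_that("feature tables are standardized with constant columns dropped", {
  prof <- simulate_cohort(13, seed = 2)
  x <- build_feature_table(prof)
  expect_equal(nrow(x), 13)
  expect_true(all(abs(colMeans(x)) < 1e-9))
  expect_true(all(abs(apply(x, 2, stats::sd) - 1) < 1e-9))
  # identical tumors give identical standardized rows
  p2 <- prof[c(1, 1, 2), ]
  p2$tumor_id <- c("a", "b", "c")
  x2 <- build_feature_table(p2)
  expect_equal(unname(x2["a", ]), unname(x2["b", ]))
  # a constant column is dropped and reported
  p3 <- prof
  p3$max_diameter_cm <- 4
  expect_message(x3 <- build_feature_table(p3), "constant")
  expect_false("max_diameter_cm" %in% colnames(x3))
  expect_equal(attr(x3, "dropped"), "max_diameter_cm")
})

test_that("missing features are reported by tumor and feature", {
  prof <- simulate_cohort(5, seed = 3)
  prof$pct_multi[2] <- NA
  expect_error(build_feature_table(prof), "pct_multi.*'2'")
  expect_error(
    build_feature_table(prof, features = c("pct_non", "nope")),
    "nope"
  )
})

test_that("PCA handles rank-1 data and conserves total variance", {
  # points on a line: one component carries everything
  x <- cbind(1:6, 2 * (1:6))
  p <- run_pca(scale(x))
  expect_equal(p$explained_pct, c(100, 0), tolerance = 1e-9)
  withr::with_seed(5, {
    y <- matrix(stats::rnorm(130), 13, 10)
    py <- run_pca(y)
    expect_equal(sum(py$explained_pct), 100, tolerance = 1e-6)
    expect_true(all(diff(py$explained_pct) <= 1e-9))
  })
  expect_error(run_pca(matrix(1, 3, 2)), "rank-0|Degenerate")
})

test_that("PCA agrees with a covariance eigendecomposition oracle", {
  withr::with_seed(11, {
    for (rep in 1:10) {
      n <- sample(3:5, 1)
      p <- sample(2:5, 1)
      x <- matrix(stats::rnorm(n * p), n, p)
      res <- run_pca(x)
      # independent oracle: eigenvalues/vectors of the covariance matrix
      eg <- eigen(stats::cov(x), symmetric = TRUE)
      ev <- pmax(eg$values, 0)
      k <- ncol(res$loadings)
      expect_equal(res$explained_pct[1:k], (100 * ev / sum(ev))[1:k],
        tolerance = 1e-8
      )
      # eigenvectors of (near-)zero eigenvalues are arbitrary; compare only
      # components carrying variance
      real <- which(ev[1:k] > 1e-8 * sum(ev))
      expect_equal(abs(res$loadings[, real, drop = FALSE]),
        abs(eg$vectors[, real, drop = FALSE]),
        tolerance = 1e-6, ignore_attr = TRUE
      )
      # sign convention: largest-|loading| entry positive
      for (j in seq_len(k)) {
        v <- res$loadings[, j]
        expect_gt(v[which.max(abs(v))], 0)
      }
    }
  })
})

test_that("two latent factors dominate the synthetic cohort variance", {
  prof <- simulate_cohort(13, seed = 1)
  p <- run_pca(build_feature_table(prof))
  expect_gte(sum(p$explained_pct[1:2]), 75)
})

test_that("clustering separates recurrent-like from non-recurrent-like", {
  prof <- simulate_cohort(13, seed = 1)
  x <- build_feature_table(prof)
  cl <- cluster_tumors(x, k = 2)
  tab <- table(cl$clusters, prof$group)
  # each generator group maps to a single cluster
  expect_equal(sum(apply(tab, 1, max)), 13)
})

test_that("clustering base cases and tie-free determinism hold", {
  x2 <- matrix(c(1, 2, 0, 5, 3, 1), nrow = 2)
  rownames(x2) <- c("a", "b")
  cl <- cluster_tumors(x2)
  expect_equal(sort(cl$order), c(1, 2))
  expect_equal(unname(cl$clusters), c(1, 2))
  # two identical tumors merge first
  x3 <- rbind(a = c(1, 2, 3), b = c(3, 1, 0.5), c = c(1, 2, 3))
  cl3 <- cluster_tumors(x3)
  expect_equal(sort(cl3$hclust$merge[1, ]), c(-3, -1))
  expect_equal(cl3$clusters[["a"]], cl3$clusters[["c"]])
  expect_error(cluster_tumors(x3, k = 5), "Fewer tumors")
})

test_that("cluster partitions are invariant to tumor order", {
  prof <- simulate_cohort(10, seed = 8)
  x <- build_feature_table(prof)
  cl1 <- cluster_tumors(x, k = 2)$clusters
  perm <- sample(nrow(x))
  cl2 <- cluster_tumors(x[perm, ], k = 2)$clusters
  # same partition up to label swap
  m <- table(cl1[rownames(x)[perm]], cl2)
  expect_equal(sum(apply(m, 1, max)), nrow(x))
})

test_that("the recurrence rule reproduces the three anchored tumors", {
  profiles <- tibble::tibble(
    tumor_id = c("2", "4", "8"),
    pct_spontaneous = c(57.4, 0, 0),
    pct_non = c(27.0, 97.9, 3.16),
    pct_mono = c(15.9, 1.0, 96.3),
    pct_multi = c(57.1, 0.1, 0.22)
  )
  out <- predict_recurrence(profiles)
  # Table 1: tumor 2 recurrent; tumors 4 and 8 not
  expect_equal(out$recurrent_predicted, c(TRUE, FALSE, FALSE))
  # rule trace: tumor 8 fails on the multi clause specifically
  expect_false(out$clause_multi[3])
  expect_true(out$clause_non[3])
})

test_that("the recurrence rule is monotone in its three inputs", {
  withr::with_seed(19, {
    for (rep in 1:50) {
      base <- tibble::tibble(
        pct_spontaneous = stats::runif(1, 0, 100),
        pct_multi = stats::runif(1, 0, 60),
        pct_non = stats::runif(1, 0, 100)
      )
      pred0 <- predict_recurrence(base)$recurrent_predicted
      up <- base
      up$pct_multi <- min(100, up$pct_multi + stats::runif(1, 0, 40))
      up$pct_spontaneous <- min(100, up$pct_spontaneous + stats::runif(1, 0, 40))
      up$pct_non <- max(0, up$pct_non - stats::runif(1, 0, 40))
      pred1 <- predict_recurrence(up)$recurrent_predicted
      expect_true(pred1 >= pred0)
    }
  })
})

test_that("percentages outside [0, 100] are rejected", {
  expect_error(
    predict_recurrence(tibble::tibble(
      pct_spontaneous = -5, pct_multi = 10, pct_non = 50
    )),
    "\\[0, 100\\]"
  )
})
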