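test_that("accuracy follows the confusion-count ratio", {
  expect_equal(accuracy(50, 50, 0, 0), 1.0)
  expect_equal(accuracy(40, 35, 15, 10), 0.75)
  expect_equal(accuracy(0, 0, 50, 50), 0.0)
  expect_error(accuracy(0, 0, 0, 0), "zero")
  cc <- confusion_counts(c(1, 1, -1, -1), c(1, -1, -1, 1))
  expect_equal(cc, list(TP = 1L, TN = 1L, FP = 1L, FN = 1L))
})

test_that("random-forest accuracy separates clusters and is seeded", {
  dat <- two_clusters(n_per = 30, sep = 6, sd = 0.5, seed = 2)
  tr <- c(1:20, 31:50); ts <- setdiff(1:60, tr)
  for (s in 1:5) {
    a <- random_forest_accuracy(dat$X, tr, dat$labels[tr], ts, dat$labels[ts],
                                seed = s)
    expect_gte(a, 0.95)
  }
  a1 <- random_forest_accuracy(dat$X, tr, dat$labels[tr], ts, dat$labels[ts],
                               seed = 3)
  a2 <- random_forest_accuracy(dat$X, tr, dat$labels[tr], ts, dat$labels[ts],
                               seed = 3)
  expect_identical(a1, a2)
  expect_error(random_forest_accuracy(dat$X, tr, rep(1L, 40), ts,
                                      dat$labels[ts]), "both classes")
})

test_that("random-forest accuracy sits at chance under permuted labels", {
  dat <- two_clusters(n_per = 30, sep = 6, sd = 0.5, seed = 4)
  accs <- vapply(1:20, function(s) {
    set.seed(s)
    perm <- sample(dat$labels)
    tr <- c(1:20, 31:50); ts <- setdiff(1:60, tr)
    if (length(unique(perm[tr])) < 2) return(NA_real_)
    random_forest_accuracy(dat$X, tr, perm[tr], ts, perm[ts], seed = s)
  }, numeric(1))
  expect_lt(abs(mean(accs, na.rm = TRUE) - 0.5), 0.1)
})

test_that("silhouette index matches hand computation and the cluster oracle", {
  Y <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  labs <- c(1L, 1L, -1L, -1L)
  expect_equal(silhouette_index(Y, labs), 0.99, tolerance = 1e-3)
  # label swap symmetry
  expect_equal(silhouette_index(Y, labs), silhouette_index(Y, -labs))
  # independent oracle: cluster::silhouette mean width (binary case)
  set.seed(6)
  Y2 <- matrix(rnorm(60), 30, 2)
  labs2 <- rep(c(1L, -1L), 15)
  ours <- silhouette_index(Y2, labs2)
  sil <- cluster::silhouette(ifelse(labs2 == 1, 1, 2), stats::dist(Y2))
  expect_equal(ours, mean(sil[, "sil_width"]), tolerance = 1e-10)
  expect_true(ours >= -1 && ours <= 1)
  expect_error(silhouette_index(Y2, c(1L, rep(-1L, 29))), "2 labelled")
})

test_that("silhouette handles coincident points and unlabeled exclusion", {
  Y <- matrix(0, 4, 1)
  expect_equal(silhouette_index(Y, c(1L, 1L, -1L, -1L)), 0)
  Y2 <- matrix(c(0, 0.1, 10, 10.1, 99), ncol = 1)
  expect_equal(silhouette_index(Y2, c(1L, 1L, -1L, -1L, 0L)),
               silhouette_index(Y2[1:4, , drop = FALSE], c(1L, 1L, -1L, -1L)))
})

test_that("score variance matches the two-pass formula", {
  expect_equal(score_variance(c(0.8, 0.9)), 0.005)
  expect_equal(score_variance(rep(0.7, 5)), 0)
  set.seed(7)
  for (rep in 1:5) {
    v <- runif(sample(3:20, 1))
    expect_equal(score_variance(v), sum((v - mean(v))^2) / (length(v) - 1))
  }
  expect_error(score_variance(0.5), "n >= 2")
})

test_that("empirical max scans runs and label counts", {
  expect_equal(empirical_max(0.8), 0.8)
  expect_equal(empirical_max(matrix(0.6, 3, 4)), 0.6)
  expect_equal(empirical_max(matrix(c(0.7, 0.75, 0.8, 0.78), 2)), 0.8)
})

test_that("Raghavan efficiency reproduces boundary and hand values", {
  expect_equal(raghavan_efficiency(c(0.6, 0.8, 0.9), c(0.6, 0.8, 0.9)), 0)
  expect_equal(raghavan_efficiency(c(0.9, 0.9, 0.9), c(0.6, 0.8, 0.9)), 1)
  expect_equal(raghavan_efficiency(c(0.8, 0.9, 0.9), c(0.6, 0.8, 0.9)), 0.75)
  expect_error(raghavan_efficiency(c(0.8, 0.9), c(0.9, 0.9)), "undefined")
  # empirical-max reference variant
  expect_equal(raghavan_efficiency(c(0.8, 0.9, 0.9), c(0.6, 0.8, 0.9),
                                   reference = "empirical_max",
                                   empirical_max = 0.9), 0.75)
})

test_that("maximum query efficiency measures label savings", {
  # AD reaches 0.9 at l = 10, SS at l = 20, N = 100
  l <- c(10, 20, 30)
  expect_equal(max_query_efficiency(c(0.9, 0.9, 0.9), c(0.5, 0.9, 0.9),
                                    l, 100), 0.10)
  expect_equal(max_query_efficiency(c(0.7, 0.8), c(0.7, 0.8), c(5, 10), 50), 0)
  # dominance implies nonnegative savings
  expect_gte(max_query_efficiency(c(0.6, 0.9), c(0.5, 0.8), c(5, 10), 50), 0)
  expect_error(max_query_efficiency(c(0.99, 0.99), c(0.1, 0.2), c(1, 2), 10),
               "never reaches")
})

test_that("maximum information gain is the largest curve gap", {
  expect_equal(max_information_gain(c(0.7, 0.8), c(0.7, 0.8)), 0)
  expect_equal(max_information_gain(c(0.75, 0.85), c(0.7, 0.8)), 0.05)
  expect_equal(max_information_gain(c(0.7, 0.85, 0.9), c(0.7, 0.8, 0.9)), 0.05)
})

test_that("efficiency improvement uses the reported sign convention", {
  expect_equal(as.numeric(efficiency_improvement(0.5, 0.5)), 0)
  expect_equal(as.numeric(efficiency_improvement(0.6, 0.5)), 20)
  d <- efficiency_improvement(0.25, 0.5)
  expect_equal(as.numeric(d), -50)
  expect_equal(attr(d, "as_printed"), 50)
  expect_error(efficiency_improvement(0.5, 0), "zero")
})
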