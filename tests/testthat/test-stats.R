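test_that("OLS recovers exact linear relations and degenerate inputs error", {
  x <- 1:10
  f <- linreg(x, 2 * x)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 0, tolerance = 1e-12)
  expect_equal(f$r2, 1)
  expect_error(linreg(rep(1, 5), 1:5), "zero variance")
  expect_error(linreg(1:2, 1:2), "at least 3")
  # direction is preserved under noise
  set.seed(2)
  fn <- linreg(x, -x + rnorm(10, sd = 0.1))
  expect_lt(fn$slope, 0)
})

test_that("R-squared equals the squared Pearson correlation", {
  set.seed(4)
  for (i in 1:10) {
    x <- rnorm(30)
    y <- 0.6 * x + rnorm(30)
    f <- linreg(x, y)
    expect_equal(f$r2, cor(x, y)^2, tolerance = 1e-12)
  }
})

test_that("independent noise yields near-zero R-squared at n = 1000", {
  set.seed(11)
  f <- linreg(rnorm(1000), rnorm(1000))
  expect_lt(f$r2, 0.02)
  expect_gt(f$p_value, 0.001)
})

test_that("confidence bands widen away from the mean of x", {
  set.seed(5)
  x <- runif(50, 0, 10)
  f <- linreg(x, 1 + 0.5 * x + rnorm(50))
  pr <- predict(f, c(5, 10), interval = "confidence")
  expect_lt(pr[1, "upr"] - pr[1, "lwr"], pr[2, "upr"] - pr[2, "lwr"])
})

test_that("Gaussian histogram fits recover mu and sigma on normal samples", {
  vals <- sample_width_distribution(20, 5, 3001, seed = 8)
  g <- gaussian_fit(vals)
  expect_equal(g$mu, 20, tolerance = 3 * 5 / sqrt(3001) * 3)
  expect_equal(g$sigma, 5, tolerance = 0.5)
  expect_gt(g$goodness, 0.9)
  expect_error(gaussian_fit(rep(3, 50)), "identical")
  expect_error(gaussian_fit(rnorm(5)), "at least 10")
})

test_that("a bimodal sample is flagged by low goodness", {
  set.seed(13)
  bim <- c(rnorm(1500, 5, 1), rnorm(1500, 25, 1))
  uni <- rnorm(3000, 15, 3)
  expect_lt(gaussian_fit(bim)$goodness, gaussian_fit(uni)$goodness)
  expect_lt(gaussian_fit(bim)$goodness, 0.8)
})

test_that("patristic distances sum branch lengths along the tree", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,(B:0.5,C:0.5):0.5);", f)
  d <- patristic_distances(f)
  expect_equal(d["B", "C"], 1)
  expect_equal(d["A", "B"], 2)
  expect_equal(d, t(d))
})

test_that("distance-binned regression reduces to the global fit for one bin", {
  set.seed(17)
  n <- 40
  ids <- paste0("s", 1:9)
  pairs <- t(utils::combn(ids, 2))
  mw <- runif(nrow(pairs), 5, 30)
  score <- -0.1 * mw + rnorm(nrow(pairs), sd = 0.2)
  tab <- data.frame(strain_a = pairs[, 1], strain_b = pairs[, 2],
                    mean_width = mw, mip = score)
  D <- matrix(runif(81, 0, 1), 9, 9, dimnames = list(ids, ids))
  D <- (D + t(D)) / 2; diag(D) <- 0
  one <- binned_distance_correlation(tab, D, c(0, 1))
  glob <- linreg(mw, score)
  expect_equal(one$r2, glob$r2)
  expect_equal(one$slope, glob$slope)
  expect_false(one$empty)
})

test_that("bins with too few pairs are flagged empty, missing distances error", {
  ids <- c("a", "b", "c", "d")
  tab <- data.frame(strain_a = c("a", "a", "a"),
                    strain_b = c("b", "c", "d"),
                    mean_width = c(1, 2, 3), mip = c(1, 0, 2))
  D <- matrix(0.2, 4, 4, dimnames = list(ids, ids)); diag(D) <- 0
  res <- binned_distance_correlation(tab, D, c(0, 0.5, 1))
  expect_true(res$empty[res$bin == "(0.5,1]"])
  expect_false(res$empty[1])
  expect_error(
    binned_distance_correlation(
      data.frame(strain_a = "a", strain_b = "zz", mean_width = 1, mip = 1),
      D, c(0, 1)),
    "no distance for pair")
})

test_that("correlation strength can be resolved per distance bin", {
  # constructed so the width-score coupling only exists at large distance
  set.seed(23)
  ids <- paste0("s", 1:30)
  pairs <- t(utils::combn(ids, 2))
  d <- runif(nrow(pairs), 0, 1)
  D <- matrix(0, 30, 30, dimnames = list(ids, ids))
  D[cbind(pairs[, 1], pairs[, 2])] <- d
  D <- D + t(D)
  mw <- runif(nrow(pairs), 5, 30)
  score <- ifelse(d > 0.5, -0.2 * mw, 0) + rnorm(nrow(pairs), sd = 0.4)
  tab <- data.frame(strain_a = pairs[, 1], strain_b = pairs[, 2],
                    mean_width = mw, mip = score)
  res <- binned_distance_correlation(tab, D, c(0, 0.5, 1))
  expect_gt(res$r2[2], res$r2[1])
})

test_that("hierarchical clustering is deterministic and recovers blocks", {
  set.seed(29)
  blockA <- matrix(rnorm(5 * 6, mean = 0), 5, 6)
  blockB <- matrix(rnorm(4 * 6, mean = 8), 4, 6)
  mat <- rbind(blockA, blockB)
  rownames(mat) <- paste0("r", 1:9)
  colnames(mat) <- paste0("c", 1:6)
  hc <- hier_cluster(mat)
  groups <- stats::cutree(hc$row, k = 2)
  expect_length(unique(groups[paste0("r", 1:5)]), 1)
  expect_length(unique(groups[paste0("r", 6:9)]), 1)
  # identical rows merge at height zero
  mat2 <- mat; mat2["r2", ] <- mat2["r1", ]
  expect_equal(min(hier_cluster(mat2)$row$height), 0)
  # row permutation does not change the result
  hc_perm <- hier_cluster(mat[sample(9), ])
  expect_equal(hc_perm$row_order, hc$row_order)
  expect_equal(hc_perm$row$merge, hc$row$merge)
  mat[1, 1] <- NA
  expect_error(hier_cluster(mat), "non-finite")
})
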