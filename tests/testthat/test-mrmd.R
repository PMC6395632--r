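test_that("relevance is the absolute Pearson correlation with the labels", {
  y <- c(1, 1, 0, 0, 1, 0)
  expect_equal(mrmd_relevance(y, y), 1)
  expect_equal(mrmd_relevance(-y, y), 1)
  expect_equal(mrmd_relevance(c(1, -1, -1, 1, 0, 0), c(1, 1, 0, 0, 1, 1)), 0)
  expect_warning(r0 <- mrmd_relevance(rep(2, 6), y), "zero-variance")
  expect_equal(r0, 0)
})

test_that("distance variants behave like distances", {
  X <- cbind(a = c(1, 0, 0), b = c(1, 0, 0), c = c(0, 1, 0))
  ed <- mrmd_distance(X, "ed")
  expect_equal(unname(ed["a"]), unname(ed["b"]))
  expect_equal(unname(ed["a"]), sqrt(2) / 2)     # 0 to b, sqrt(2) to c
  # orthogonal unit columns: cosine dissimilarity 1
  U <- cbind(u = c(1, 0), v = c(0, 1))
  expect_equal(unname(mrmd_distance(U, "cos")), c(1, 1))
  expect_equal(unname(mrmd_distance(U, "tc")), c(1, 1))
  # identical columns are at distance 0 under all variants
  I2 <- cbind(p = c(0.3, 0.7), q = c(0.3, 0.7))
  for (v in c("ed", "cos", "tc", "mean"))
    expect_equal(unname(mrmd_distance(I2, v)), c(0, 0), tolerance = 1e-12)
  # mean is the entrywise average of the three
  set.seed(2)
  M <- matrix(runif(40), ncol = 4, dimnames = list(NULL, letters[1:4]))
  expect_equal(mrmd_distance(M, "mean"),
               (mrmd_distance(M, "ed") + mrmd_distance(M, "cos") +
                  mrmd_distance(M, "tc")) / 3)
  expect_error(mrmd_distance(M[, 1, drop = FALSE]), "two features")
})

test_that("weight limits reduce MRMD to pure relevance or pure distance", {
  set.seed(12)
  X <- matrix(runif(120), ncol = 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  y <- rbinom(20, 1, 0.5); y[1] <- 1; y[2] <- 0
  rel <- apply(X, 2, function(c) abs(cor(c, y)))
  dst <- mrmd_distance(X, "ed")
  expect_equal(mrmd_rank(X, y, "ed", w_d = 0)$order,
               names(sort(rel, decreasing = TRUE)))
  expect_equal(mrmd_rank(X, y, "ed", w_r = 0)$order,
               names(sort(dst, decreasing = TRUE)))
})

test_that("a duplicated feature never outranks its original when w_d > 0", {
  # brute-force on a small toy matrix: the duplicate has identical
  # relevance but its mean distance can only be <= the original's
  # (both lose the same pairwise terms except the zero to each other)
  set.seed(3)
  base <- matrix(runif(50), ncol = 5,
                 dimnames = list(NULL, paste0("f", 1:5)))
  y <- rbinom(10, 1, 0.5); y[1] <- 1; y[2] <- 0
  X <- cbind(base, dup = base[, 2])
  for (v in c("ed", "cos", "tc", "mean")) {
    rk <- mrmd_rank(X, y, v)
    expect_lt(which(rk$order == "f2"), which(rk$order == "dup"))
  }
})

test_that("MRMD ranking is permutation-equivariant", {
  set.seed(19)
  X <- matrix(rnorm(80), ncol = 4,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  y <- rep(c(1, 0), 10)
  rk <- mrmd_rank(X, y, "mean")
  rk_p <- mrmd_rank(X[, c(4, 2, 1, 3)], y, "mean")
  expect_equal(rk_p$order, rk$order)
  expect_equal(rk_p$scores, rk$scores)
})

test_that("planted feature outranks noise under IG and every MRMD variant", {
  # one informative feature among 50 pure-noise features of commensurate
  # scale (MRMD's distance term presumes commensurate features, as the
  # package's bounded encoder outputs are); the planted column separates
  # the classes around zero so presence-binarization sees it too
  set.seed(101)
  n <- 600
  y <- rep(c(1L, 0L), n / 2)
  planted <- (y - 0.5) + rnorm(n, 0, 0.3)
  noise <- matrix(rnorm(n * 50, 0, 0.5), ncol = 50,
                  dimnames = list(NULL, paste0("noise", 1:50)))
  X <- cbind(noise[, 1:25], planted = planted, noise[, 26:50])
  for (v in c("ed", "cos", "tc", "mean"))
    expect_equal(mrmd_rank(X, y, v)$order[1], "planted",
                 info = paste("variant", v))
  expect_equal(rank_features_ig(X, y)$order[1], "planted")
})
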