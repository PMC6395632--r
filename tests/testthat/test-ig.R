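test_that("binarization is a presence indicator and idempotent", {
  expect_equal(binarize_presence(c(0, 0.3, 0)), c(0, 1, 0))
  m <- matrix(c(0, 0, 0, 0.2, 0, 1.5), ncol = 2)
  b <- binarize_presence(m)
  expect_equal(b[, 1], rep(0, 3))
  expect_identical(binarize_presence(b), b)
  expect_equal(binarize_presence(c(0.1, 0.6), threshold = 0.5), c(0, 1))
})

test_that("information gain equals brute-force mutual information on all
           2x2 patterns up to n = 12", {
  for (n in 2:12) {
    for (n11 in 0:n) for (n10 in 0:(n - n11)) for (n01 in 0:(n - n11 - n10)) {
      n00 <- n - n11 - n10 - n01
      if (n11 + n10 == 0 || n01 + n00 == 0) next  # single-class labels
      v <- vectors_from_counts(n11, n10, n01, n00)
      expect_equal(information_gain(v$feature, v$labels),
                   mi_oracle(n11, n10, n01, n00),
                   tolerance = 1e-12,
                   info = sprintf("pattern %d/%d/%d/%d", n11, n10, n01, n00))
    }
  }
})

test_that("information gain handles the canonical examples", {
  expect_equal(information_gain(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(information_gain(c(1, 0, 1, 0), c(1, 1, 0, 0)), 0)
  expect_equal(information_gain(c(1, 1, 1, 0), c(1, 1, 0, 0)),
               mi_oracle(2, 0, 1, 1), tolerance = 1e-12)
  expect_equal(information_gain(c(1, 1, 1, 0), c(1, 1, 0, 0)),
               0.3112781, tolerance = 1e-6)
  expect_error(information_gain(c(1, 0), c(1, 1, 0)), "length")
  expect_error(information_gain(c(1, 0, 1), c(1, 1, 1)), "both classes")
})

test_that("information gain is invariant to 0/1 swaps of either argument", {
  set.seed(77)
  for (i in 1:20) {
    f <- rbinom(30, 1, 0.4)
    y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    ig <- information_gain(f, y)
    expect_equal(information_gain(1 - f, y), ig)
    expect_equal(information_gain(f, 1 - y), ig)
    expect_equal(information_gain(1 - f, 1 - y), ig)
  }
})

test_that("residue and dipeptide IG rankings recover a planted signal", {
  d <- simulate_dataset(500, 500, t = 10, seed = 1)
  rk <- rank_residue_ig(d)
  expect_equal(rk$order[1], "K")
  expect_true(all(diff(rk$scores) <= 0))
  expect_true(all(rk$scores >= 0))

  # shuffled labels drive the maximum IG toward zero
  set.seed(4)
  d_null <- sno_dataset(d$peptide, label = sample(d$label))
  expect_lt(max(rank_residue_ig(d_null)$scores), 0.02)

  # plant an adjacent M-G pair upstream of the center: its dipeptide
  # dominates the de-centered dipeptide ranking
  motif <- motif_spec(signals = data.frame(
    offset = c(-2L, -1L), residue = c("M", "G"),
    p_pos = c(0.9, 0.9), p_neg = c(0.05, 0.05)))
  d2 <- simulate_dataset(400, 400, t = 10, motif = motif, seed = 2)
  rk2 <- rank_dipeptide_ig(d2)
  expect_equal(rk2$order[1], "MG")
})

test_that("position IG peaks at the planted offset", {
  d <- simulate_dataset(400, 400, t = 10, seed = 1)
  rk <- rank_position_ig(d)
  expect_equal(rk$order[1], "m1")
})

test_that("feature-matrix IG ranking is stable and permutation-equivariant", {
  set.seed(31)
  X <- cbind(a = rbinom(60, 1, 0.5), b = rbinom(60, 1, 0.5),
             c = rbinom(60, 1, 0.5), d = rbinom(60, 1, 0.5))
  y <- rbinom(60, 1, 0.5)
  if (length(unique(y)) < 2) y[1] <- 1 - y[1]
  rk <- rank_features_ig(X, y)
  perm <- c(3, 1, 4, 2)
  rk_p <- rank_features_ig(X[, perm], y)
  # permuting columns permutes the ranking: per-feature scores agree
  expect_equal(stats::setNames(rk_p$scores, rk_p$order)[rk$order],
               stats::setNames(rk$scores, rk$order))
  expect_equal(sort(rk_p$scores), sort(rk$scores))
  # identical columns tie; stable sort keeps original column order
  X2 <- cbind(z1 = X[, 1], z2 = X[, 1])
  rk2 <- rank_features_ig(X2, y)
  expect_equal(rk2$order, c("z1", "z2"))
})
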