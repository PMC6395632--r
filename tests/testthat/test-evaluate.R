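test_that("a separable problem is classified perfectly", {
  d <- separable_dataset(12)
  cfg <- sno_config(encoders = c("bpb", "kmer1"), seed = 1)
  res <- train_predict(d, d, cfg)
  expect_equal(res$metrics$acc, 1)
  expect_equal(res$metrics$mcc, 1)
  expect_equal(nrow(res$predictions), nrow(d))
})

test_that("the fitted model object predicts new windows and proteins", {
  d <- simulate_dataset(80, 80, t = 10, seed = 3)
  m <- sno_fit(d, encoders = c("bpb", "anbpb"), seed = 3)
  expect_s3_class(m, "sno_model")
  expect_output(print(m), "sno_model")
  p <- predict(m, d)
  expect_equal(nrow(p), 160)
  expect_true(all(p$label %in% c(0L, 1L)))
  # prediction accuracy on the training motif data beats chance
  expect_gt(mean(p$label == d$label), 0.7)
  # a protein sequence gets windows extracted around each cysteine
  prot <- paste0(strrep("A", 15), "C", strrep("K", 3), "C", strrep("A", 15))
  pp <- predict(m, prot)
  expect_equal(nrow(pp), 2)
  expect_true("site_position" %in% names(pp))
})

test_that("cross-validation is deterministic given a seed and counts add up", {
  d <- simulate_dataset(40, 40, t = 5, seed = 6)
  cfg <- sno_config(encoders = c("bpb"), seed = 11)
  cv1 <- cross_validate(d, k = 5, repeats = 2, config = cfg)
  cv2 <- cross_validate(d, k = 5, repeats = 2, config = cfg)
  expect_identical(cv1$mean, cv2$mean)
  expect_length(cv1$per_repeat, 2)
  for (m in cv1$per_repeat)
    expect_equal(m$tp + m$fp + m$tn + m$fn, nrow(d))
  # max summary is the best repeat by accuracy
  accs <- vapply(cv1$per_repeat, `[[`, numeric(1), "acc")
  expect_equal(cv1$max$acc, max(accs))
})

test_that("jackknife runs one fit per window", {
  d <- simulate_dataset(12, 12, t = 4, seed = 2)
  cfg <- sno_config(encoders = "kmer1", classifier = "logistic", seed = 1)
  fits <- 0L
  counting <- cfg
  counting$classifier <- list(
    name = "counting",
    fit = function(x, y) { fits <<- fits + 1L; cfg$classifier$fit(x, y) },
    predict = cfg$classifier$predict)
  cv <- cross_validate(d, scheme = "jackknife", config = counting)
  expect_equal(fits, nrow(d))
  expect_equal(cv$k, nrow(d))
  expect_equal(cv$repeats, 1L)
})

test_that("label-shuffled data scores near chance with fold-wise refits", {
  d <- simulate_dataset(60, 60, t = 5, seed = 13)
  set.seed(13)
  d_null <- sno_dataset(d$peptide, label = sample(d$label))
  cfg <- sno_config(encoders = c("bpb", "dbpb"), seed = 13)
  cv <- cross_validate(d_null, k = 5, config = cfg)
  # 3 standard errors of a fair coin at n = 120
  se3 <- 3 * sqrt(0.25 / nrow(d_null))
  expect_lt(abs(cv$mean$acc - 0.5), se3 + 0.05)
})

test_that("paper-mode profile fitting leaks and fold-wise fitting does not", {
  # pure positional noise: no true signal, so honest CV stays near 0.5
  # while whole-set profile fitting lets the fold classifier see its
  # test windows' class-conditional frequencies
  d <- simulate_dataset(50, 50, t = 5,
                        motif = motif_spec(signals = data.frame(
                          offset = -1L, residue = "K",
                          p_pos = 0, p_neg = 0)),
                        seed = 21)
  cfg <- sno_config(encoders = "bpb", seed = 21)
  honest <- cross_validate(d, k = 5, config = cfg)
  leaky <- cross_validate(d, k = 5, config = cfg, paper_mode = TRUE)
  se3 <- 3 * sqrt(0.25 / nrow(d))
  expect_lt(abs(honest$mean$acc - 0.5), se3 + 0.05)
  expect_gt(leaky$mean$acc, honest$mean$acc)
})

test_that("train/test guards fire", {
  d5 <- simulate_dataset(5, 5, t = 5, seed = 1)
  d6 <- simulate_dataset(5, 5, t = 6, seed = 1)
  expect_error(train_predict(d5, d6), "half-widths differ")
  expect_error(cross_validate(d5, k = 50), "must not exceed")
})
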