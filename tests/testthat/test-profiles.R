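make_profile <- function(n = 12L, t = 10L, seed = 5L) {
  d <- simulate_dataset(n, n, t = t, seed = seed)
  list(data = d, profile = fit_positional_profiles(d))
}

test_that("profile encoders reproduce the standard dimensions at t = 10", {
  fx <- make_profile()
  w <- fx$data$peptide[1]
  expect_length(encode_bpb(w, fx$profile), 40)
  expect_length(encode_anbpb(w, fx$profile), 40)
  expect_length(encode_dbpb(w, fx$profile), 38)
  expect_length(encode_iaapair(w, fx$profile), 39)
  expect_length(encode_pstaap(w, fx$profile), 18)
})

test_that("profile encoder values respect their ranges", {
  fx <- make_profile(n = 25L, seed = 11L)
  for (w in fx$data$peptide[1:10]) {
    for (enc in list(encode_bpb, encode_anbpb, encode_dbpb)) {
      v <- enc(w, fx$profile)
      expect_true(all(v >= 0 & v <= 1))
    }
    for (enc in list(encode_iaapair, encode_pstaap)) {
      v <- enc(w, fx$profile)
      expect_true(all(v >= -1 & v <= 1))
    }
  }
})

test_that("a single-window class gives probability one to what it saw", {
  t <- 5L
  pos <- "AKDEFCGHIKL"
  neg <- "LKIHGCFEDKA"
  d <- sno_dataset(c(pos, neg), label = c(1L, 0L))
  pr <- fit_positional_profiles(d)
  expect_equal(unname(encode_bpb(pos, pr)[1:(2 * t)]), rep(1, 2 * t))
  expect_equal(unname(encode_dbpb(pos, pr)[1:(2 * t - 1)]),
               rep(1, 2 * t - 1))
  # a residue never seen at a position scores 0
  other <- "WWWWWCWWWWW"
  expect_equal(unname(encode_bpb(other, pr)[1:(2 * t)]), rep(0, 2 * t))
})

test_that("identical classes zero the difference encoders and equal the blocks", {
  d0 <- simulate_dataset(8, 8, t = 6, seed = 2)
  d <- sno_dataset(rep(d0$peptide[1:8], 2),
                   label = rep(c(1L, 0L), each = 8))
  pr <- fit_positional_profiles(d)
  for (w in d$peptide[1:4]) {
    expect_equal(unname(encode_iaapair(w, pr)), rep(0, 23))
    expect_equal(unname(encode_pstaap(w, pr)), rep(0, 10))
    b <- encode_bpb(w, pr)
    expect_equal(unname(b[1:12]), unname(b[13:24]))
  }
})

test_that("swapping class labels negates the difference encoders", {
  d <- simulate_dataset(10, 10, t = 6, seed = 8)
  sw <- sno_dataset(d$peptide, label = 1L - d$label)
  pr <- fit_positional_profiles(d)
  pr_sw <- fit_positional_profiles(sw)
  for (w in d$peptide[1:5]) {
    expect_equal(encode_iaapair(w, pr_sw), -encode_iaapair(w, pr))
    expect_equal(encode_pstaap(w, pr_sw), -encode_pstaap(w, pr))
  }
})

test_that("the adapted-normal transform is monotone and 0.5 at uniformity", {
  fx <- make_profile(n = 30L, seed = 13L)
  pr <- fx$profile
  # monotone: within a position, higher class frequency never encodes lower
  singles <- pr$pos$singles
  pos_j <- 3L
  freqs <- singles[, pos_j] / pr$n_pos
  letters <- rownames(singles)
  enc_at <- function(letter) {
    w <- fx$data$peptide[1]
    substr(w, pos_j, pos_j) <- letter
    encode_anbpb(w, pr)[pos_j]
  }
  vals <- vapply(letters, enc_at, numeric(1))
  ord <- order(freqs)
  expect_true(all(diff(vals[ord]) >= -1e-12))

  # a position where all 21 letters are equally frequent encodes 0.5:
  # emulate by a degenerate profile whose counts are identical
  pru <- pr
  pru$pos$singles[] <- 1L
  pru$n_pos <- 21L
  expect_equal(unname(encode_anbpb(fx$data$peptide[1], pru)[1:20]),
               rep(0.5, 20))
})

test_that("profiles survive a JSON round trip bit-exactly", {
  fx <- make_profile(n = 9L, t = 7L, seed = 21L)
  path <- tempfile(fileext = ".json")
  write_profiles(fx$profile, path)
  pr2 <- read_profiles(path)
  for (w in fx$data$peptide[1:5]) {
    expect_identical(encode_bpb(w, fx$profile), encode_bpb(w, pr2))
    expect_identical(encode_anbpb(w, fx$profile), encode_anbpb(w, pr2))
    expect_identical(encode_dbpb(w, fx$profile), encode_dbpb(w, pr2))
    expect_identical(encode_iaapair(w, fx$profile), encode_iaapair(w, pr2))
    expect_identical(encode_pstaap(w, fx$profile), encode_pstaap(w, pr2))
  }
})

test_that("profile fitting rejects unusable training sets", {
  d <- simulate_dataset(5, 5, t = 4, seed = 1)
  only_pos <- sno_dataset(d$peptide[d$label == 1], label = 1L)
  expect_error(fit_positional_profiles(only_pos), "both classes")
  pr <- fit_positional_profiles(d)
  expect_error(encode_bpb("AAACAAA", pr), "does not match")
})
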