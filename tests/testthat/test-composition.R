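test_that("index standardization gives zero mean and unit mean square", {
  idx <- sno_indices()
  expect_equal(unname(rowMeans(idx$standardized)), rep(0, 3),
               tolerance = 1e-12)
  expect_equal(unname(rowMeans(idx$standardized^2)), rep(1, 3),
               tolerance = 1e-12)

  # an index already at mean 0 / mean-square 1 is left unchanged
  half <- c(rep(1, 10), rep(-1, 10))
  names(half) <- sno_alphabet(FALSE)
  expect_equal(standardize_indices(rbind(half))[1, ], half)

  # arbitrary distinct values: compare against a one-line reference
  set.seed(9)
  v <- stats::setNames(rnorm(20, 50, 12), sno_alphabet(FALSE))
  ref <- (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  expect_equal(standardize_indices(rbind(v))[1, ], ref)
  expect_equal(mean(standardize_indices(rbind(v))[1, ]^2), 1,
               tolerance = 1e-12)

  expect_error(standardize_indices(rbind(rep(3, 20))), "degenerate")
})

test_that("custom index tables load from TSV and standardize", {
  path <- tempfile(fileext = ".tsv")
  set.seed(8)
  df <- data.frame(aa = sno_alphabet(FALSE), charge = rnorm(20),
                   bulk = runif(20, 10, 130))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  idx <- read_index_tsv(path)
  expect_equal(rownames(idx$raw), c("charge", "bulk"))
  expect_equal(unname(idx$raw["bulk", df$aa]), df$bulk)
  expect_equal(unname(rowMeans(idx$standardized)), c(0, 0),
               tolerance = 1e-12)
  bad <- df[-1, ]
  utils::write.table(bad, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_index_tsv(path), "20 standard amino acids")
})

test_that("theta correlation is symmetric, non-negative and zero on equals", {
  idx <- sno_indices()
  for (pair in list(c("A", "A"), c("K", "R"), c("W", "G"))) {
    th <- theta_correlation(pair[1], pair[2], idx)
    expect_gte(th, 0)
    expect_equal(th, theta_correlation(pair[2], pair[1], idx))
  }
  expect_equal(theta_correlation("A", "A", idx), 0)
  # single-index general mode reduces to the squared difference
  one <- sno_indices(sno_indices()$raw["hydrophobicity", , drop = FALSE])
  h <- one$standardized[1, ]
  expect_equal(theta_correlation("K", "W", one, mode = "general"),
               (h[["K"]] - h[["W"]])^2)
})

test_that("pseudo amino acid composition matches its defining identities", {
  v <- encode_pc_pseaac("AAAA", lam = 1, w = 0.5)
  expect_equal(unname(v[["f.A"]]), 1)         # theta(A,A)=0 so tail is 0
  expect_equal(unname(v[["theta.1"]]), 0)

  seqs <- c("AAAAAAAAAACAAAAAAAAAA", "MKVLCDEWYRCHHIKLCNPQT",
            "XXXXXKKKKKCKKKKKXXXXX")
  for (s in seqs) {
    v5 <- encode_pc_pseaac(s, lam = 5, w = 0.5)
    expect_length(v5, 25)
    expect_equal(sum(v5), 1, tolerance = 1e-9)
    expect_true(all(v5 >= 0 & v5 <= 1))
    # w = 0 collapses to the plain normalized composition
    v0 <- encode_pc_pseaac(s, lam = 5, w = 0)
    expect_equal(unname(sum(v0[21:25])), 0)
    chars <- strsplit(s, "")[[1]]
    chars <- chars[chars != "X"]
    comp <- as.numeric(table(factor(chars, levels = sno_alphabet(FALSE)))) /
      length(chars)
    expect_equal(unname(v0[1:20]), comp, tolerance = 1e-12)
  }

  expect_error(encode_pc_pseaac("ACA", lam = 5), "effective length")
  expect_error(encode_pc_pseaac("XXX", lam = 0), "no standard residue")
})

test_that("general-mode PseAAC with the classic three indices equals PC-PseAAC", {
  s <- "MKVLCDEWYRCHHIKLCNPQT"
  v3 <- encode_pc_pseaac(s, lam = 4, w = 0.3, mode = "pcpseaac3")
  vg <- encode_pc_pseaac(s, lam = 4, w = 0.3, mode = "general")
  expect_equal(unname(vg), unname(v3), tolerance = 1e-12)
})

test_that("larger w moves mass into the correlation tail", {
  s <- "MKVLCDEWYRCHHIKLCNPQT"
  tails <- vapply(c(0.1, 0.5, 0.9), function(w)
    sum(encode_pc_pseaac(s, lam = 5, w = w)[21:25]), numeric(1))
  expect_true(all(diff(tails) > 0))
})

test_that("kmer frequencies count X-free k-mers and sum to one", {
  v1 <- encode_kmer("ACAC", k = 1)
  expect_equal(unname(v1[c("A", "C")]), c(0.5, 0.5))
  expect_equal(sum(v1), 1)

  v2 <- encode_kmer("ACAC", k = 2)
  expect_length(v2, 400)
  expect_equal(unname(v2[["AC"]]), 2 / 3)
  expect_equal(unname(v2[["CA"]]), 1 / 3)
  expect_equal(sum(v2), 1, tolerance = 1e-9)

  # X interrupts k-mers: AXC has no X-free dimer
  expect_error(encode_kmer("AXC", k = 2), "no X-free")
  v <- encode_kmer("AXXCA", k = 2)
  expect_equal(unname(v[["CA"]]), 1)
})

test_that("composition is permutation-invariant but the theta tail is not", {
  s <- "MKVLDEWYRCAHHIKLNPQTS"
  perm <- "CKLMVDEWYRAHHIKLNPQTS"  # same multiset, different order
  expect_equal(sort(strsplit(s, "")[[1]]), sort(strsplit(perm, "")[[1]]))
  a <- encode_pc_pseaac(s, lam = 5, w = 0.5)
  b <- encode_pc_pseaac(perm, lam = 5, w = 0.5)
  expect_equal(encode_kmer(s, 1), encode_kmer(perm, 1))
  # identical frequency blocks up to the shared denominator's tail effect
  expect_false(isTRUE(all.equal(unname(a[21:25]), unname(b[21:25]))))
})
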