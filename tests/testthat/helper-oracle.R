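# Brute-force plug-in mutual information (bits) from the 2x2 table of
# (label, feature) counts. Kept deliberately independent of the
# package's entropy-difference implementation: it sums
# p * log2(p / (p_row * p_col)) over the four cells.
mi_oracle <- function(n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  p <- c(n11, n10, n01, n00) / n
  prow <- c(n11 + n10, n11 + n10, n01 + n00, n01 + n00) / n  # label margin
  pcol <- c(n11 + n01, n10 + n00, n11 + n01, n10 + n00) / n  # feature margin
  keep <- p > 0
  sum(p[keep] * log2(p[keep] / (prow[keep] * pcol[keep])))
}

# Expand a 2x2 count pattern into label/feature vectors.
vectors_from_counts <- function(n11, n10, n01, n00) {
  list(labels = c(rep(1L, n11 + n10), rep(0L, n01 + n00)),
       feature = c(rep(1L, n11), rep(0L, n10), rep(1L, n01), rep(0L, n00)))
}

# A tiny strictly separable window set: positives carry K at offset -1,
# negatives carry D there; everything else alanine.
separable_dataset <- function(n_per_class = 10L, t = 10L) {
  flank <- strrep("A", t - 1L)
  pos <- paste0(strrep("A", t), "C", strrep("A", t))
  pos <- paste0(flank, "KC", strrep("A", t))
  neg <- paste0(flank, "DC", strrep("A", t))
  sno_dataset(rep(c(pos, neg), each = n_per_class),
              label = rep(c(1L, 0L), each = n_per_class))
}
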