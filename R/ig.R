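# Information-gain feature scoring: IG(class | feature) = H(class) -
# H(class | feature), in bits, with features reduced to binary presence.

#' Binarize a feature matrix to presence/absence
#'
#' Entries strictly greater than `threshold` become 1, all others 0.
#' This is the reduction under which information gain counts
#' presence/absence events.
#'
#' @param matrix numeric matrix or vector.
#' @param threshold presence cut-off (default 0: any positive value
#'   counts as present).
#' @return Object of the same shape with 0/1 entries.
#' @examples
#' binarize_presence(c(0, 0.3, 0))
#' @export
binarize_presence <- function(matrix, threshold = 0) {
  out <- (matrix > threshold) + 0L
  attributes(out) <- attributes(matrix)
  out
}

.h2 <- function(p) {
  # entropy (bits) of a probability vector, with 0 log 0 := 0
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Information gain of a binary feature about binary labels
#'
#' `IG = H(labels) - H(labels | feature)`, in bits, computed from the
#' 2x2 contingency counts; `0 log 0` is taken as 0. For binary labels
#' the result lies in `[0, 1]` bits and is 0 exactly when feature and
#' labels are empirically independent.
#'
#' @param feature binary (0/1) vector.
#' @param labels binary (0/1) vector of the same length, containing both
#'   classes.
#' @return Information gain in bits.
#' @examples
#' information_gain(c(1, 1, 0, 0), c(1, 1, 0, 0))  # 1 bit
#' information_gain(c(1, 0, 1, 0), c(1, 1, 0, 0))  # 0
#' @export
information_gain <- function(feature, labels) {
  if (length(feature) != length(labels))
    stop("feature and labels must have the same length")
  labels <- as.integer(labels)
  feature <- as.integer(feature != 0L)
  if (length(unique(labels)) < 2L)
    stop("labels must contain both classes")
  n <- length(labels)
  hx <- .h2(c(mean(labels), 1 - mean(labels)))
  hxy <- 0
  for (y in c(0L, 1L)) {
    ny <- sum(feature == y)
    if (ny == 0L) next
    p1 <- sum(labels == 1L & feature == y) / ny
    hxy <- hxy + (ny / n) * .h2(c(p1, 1 - p1))
  }
  hx - hxy
}

# Stable descending ranking helper shared by IG and MRMD.
.ranked <- function(names, scores, method) {
  ord <- order(-scores)  # order() is stable: ties keep original order
  structure(list(order = names[ord],
                 scores = scores[ord],
                 method = method),
            class = "sno_ranking")
}

#' @export
print.sno_ranking <- function(x, n = 10L, ...) {
  cat(sprintf("sno_ranking (%s): %d features\n", x$method,
              length(x$order)))
  k <- min(n, length(x$order))
  print(data.frame(feature = x$order[seq_len(k)],
                   score = signif(x$scores[seq_len(k)], 4)))
  if (length(x$order) > k) cat("  ...\n")
  invisible(x)
}

#' Rank features of a matrix by information gain
#'
#' Binarizes each column to presence/absence and scores it against the
#' labels with [information_gain()]; features are sorted by descending
#' score, ties keeping their original column order.
#'
#' @param X numeric feature matrix with column names.
#' @param labels binary labels, one per row.
#' @param threshold presence cut-off passed to [binarize_presence()].
#' @return An `sno_ranking`: list with `order` (feature names, best
#'   first), `scores` (IG in bits, same order) and `method = "ig"`.
#' @export
rank_features_ig <- function(X, labels, threshold = 0) {
  B <- binarize_presence(X, threshold)
  scores <- apply(B, 2L, information_gain, labels = labels)
  .ranked(colnames(X), as.numeric(scores), "ig")
}

#' Rank residues, dipeptides or positions by information gain
#'
#' `rank_residue_ig` scores each of the 20 amino acids by the IG of its
#' presence anywhere in the window (center excluded) about the label;
#' `rank_dipeptide_ig` does the same for the 400 dipeptides of the
#' de-centered window; `rank_position_ig` scores each non-center
#' position using the residue identity there as a 21-category
#' conditioning variable.
#'
#' @param dataset a labeled [sno_dataset].
#' @return An `sno_ranking` (see [rank_features_ig()]).
#' @examples
#' d <- simulate_dataset(200, 200, t = 10, seed = 1)
#' head(rank_residue_ig(d)$order)   # the planted residue ranks first
#' @export
rank_residue_ig <- function(dataset) {
  M <- peptide_matrix(dataset$peptide)
  D <- M[, -(window_t(dataset) + 1L), drop = FALSE]
  presence <- vapply(AA20, function(a) rowSums(D == a) > 0L,
                     logical(nrow(D))) + 0L
  scores <- apply(presence, 2L, information_gain, labels = dataset$label)
  .ranked(AA20, as.numeric(scores), "ig")
}

#' @rdname rank_residue_ig
#' @export
rank_dipeptide_ig <- function(dataset) {
  M <- peptide_matrix(dataset$peptide)
  D <- M[, -(window_t(dataset) + 1L), drop = FALSE]
  m <- ncol(D)
  keys <- matrix(paste0(D[, -m], D[, -1L]), nrow = nrow(D))
  lev <- paste0(rep(AA20, each = 20L), AA20)
  presence <- vapply(lev, function(dp) rowSums(keys == dp) > 0L,
                     logical(nrow(D))) + 0L
  scores <- apply(presence, 2L, information_gain, labels = dataset$label)
  .ranked(lev, as.numeric(scores), "ig")
}

#' Residue frequency matrix of the de-centered windows
#'
#' One row per window, one column per standard amino acid, holding the
#' residue's relative frequency in the window with the center cysteine
#' excluded. This is the continuous residue-level representation used
#' when ranking residues with correlation-based methods such as MRMD
#' (information gain uses the binarized presence of the same columns).
#'
#' @param dataset an [sno_dataset].
#' @return Numeric matrix (windows x 20 residues).
#' @export
residue_frequency_matrix <- function(dataset) {
  M <- peptide_matrix(dataset$peptide)
  D <- M[, -(window_t(dataset) + 1L), drop = FALSE]
  vapply(AA20, function(a) rowSums(D == a) / ncol(D),
         numeric(nrow(D)))
}

#' @rdname rank_residue_ig
#' @export
rank_position_ig <- function(dataset) {
  M <- peptide_matrix(dataset$peptide)
  t <- window_t(dataset)
  D <- M[, -(t + 1L), drop = FALSE]
  labels <- dataset$label
  n <- length(labels)
  hx <- .h2(c(mean(labels), 1 - mean(labels)))
  scores <- apply(D, 2L, function(col) {
    hxy <- 0
    for (a in unique(col)) {
      sel <- col == a
      p1 <- mean(labels[sel])
      hxy <- hxy + (sum(sel) / n) * .h2(c(p1, 1 - p1))
    }
    hx - hxy
  })
  .ranked(.offset_labels(t), as.numeric(scores), "ig")
}
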