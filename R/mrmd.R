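# Max-relevance max-distance (MRMD) feature ranking: combine the
# absolute Pearson correlation of each feature with the label
# (relevance) with its mean distance to the other features (redundancy
# proxy; more distant = less redundant).

#' Relevance of a feature to the labels (absolute Pearson correlation)
#'
#' @param feature numeric vector.
#' @param labels numeric (0/1) vector of the same length.
#' @return `|cor(feature, labels)|` in `[0, 1]`; a zero-variance feature
#'   gets relevance 0 with a warning.
#' @export
mrmd_relevance <- function(feature, labels) {
  if (length(feature) != length(labels))
    stop("feature and labels must have the same length")
  if (stats::sd(feature) == 0 || stats::sd(labels) == 0) {
    warning("zero-variance input: relevance defined as 0", call. = FALSE)
    return(0)
  }
  abs(stats::cor(feature, labels))
}

#' Mean inter-feature distances for MRMD
#'
#' For each feature (column) computes its mean distance to every other
#' column under one of three dissimilarities: Euclidean distance
#' (`"ed"`), cosine dissimilarity `1 - cos` (`"cos"`), one minus the
#' Tanimoto coefficient (`"tc"`), or their arithmetic mean (`"mean"`).
#' Cosine and Tanimoto are similarity measures; MRMD needs larger =
#' more distant, hence the `1 -` form.
#'
#' @param matrix numeric feature matrix with at least two columns.
#' @param variant one of `"ed"`, `"cos"`, `"tc"`, `"mean"`.
#' @return Named numeric vector, one mean distance per feature.
#' @export
mrmd_distance <- function(matrix, variant = c("ed", "cos", "tc", "mean")) {
  variant <- match.arg(variant)
  X <- as.matrix(matrix)
  M <- ncol(X)
  if (M < 2L) stop("mrmd_distance needs at least two features")
  G <- crossprod(X)                       # gram matrix of columns
  sq <- diag(G)
  per_variant <- function(v) {
    D <- switch(v,
      ed = {
        d2 <- outer(sq, sq, "+") - 2 * G
        d2[d2 < 0] <- 0                  # numeric fuzz
        sqrt(d2)
      },
      cos = {
        nrm <- sqrt(sq)
        denom <- outer(nrm, nrm)
        cs <- ifelse(denom > 0, G / denom, 0)
        1 - cs
      },
      tc = {
        denom <- outer(sq, sq, "+") - G
        tcm <- ifelse(denom != 0, G / denom, 0)
        1 - tcm
      })
    (rowSums(D) - diag(D)) / (M - 1)
  }
  out <- if (variant == "mean") {
    (per_variant("ed") + per_variant("cos") + per_variant("tc")) / 3
  } else {
    per_variant(variant)
  }
  names(out) <- colnames(X)
  out
}

#' MRMD feature ranking
#'
#' Scores each feature as `w_r * relevance + w_d * distance`, where
#' relevance is the absolute Pearson correlation with the labels and
#' distance is the chosen mean inter-feature distance. By default the
#' raw distance is added to the relevance (the original MRMD
#' combination); `scale_distance = TRUE` min-max scales the distances to
#' `[0, 1]` first, which makes the two terms commensurate but lets
#' chance-level distance differences among near-exchangeable features
#' dominate the ranking. Features are sorted by descending score with
#' stable ties.
#'
#' @param matrix numeric feature matrix with column names.
#' @param labels binary labels, one per row.
#' @param variant distance variant, see [mrmd_distance()].
#' @param w_r,w_d weights of the relevance and distance terms.
#' @param scale_distance min-max scale distances before combining.
#' @return An `sno_ranking` with `method = "mrmd-<variant>"`.
#' @examples
#' X <- cbind(a = c(1, 1, 0, 0), b = c(1, 0, 1, 0))
#' mrmd_rank(X, c(1, 1, 0, 0))$order
#' @export
mrmd_rank <- function(matrix, labels, variant = c("ed", "cos", "tc", "mean"),
                      w_r = 1, w_d = 1, scale_distance = FALSE) {
  variant <- match.arg(variant)
  X <- as.matrix(matrix)
  rel <- apply(X, 2L, function(col) {
    if (stats::sd(col) == 0) 0 else abs(stats::cor(col, labels))
  })
  dist <- mrmd_distance(X, variant)
  if (scale_distance) {
    rng <- range(dist)
    dist <- if (diff(rng) > 0) (dist - rng[1L]) / diff(rng)
            else rep(0, length(dist))
  }
  .ranked(colnames(X), as.numeric(w_r * rel + w_d * dist),
          paste0("mrmd-", variant))
}
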