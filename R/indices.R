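# Physicochemical index tables and their standardization.

# Chou's original hydrophobicity, Hopp-Woods hydrophilicity and side-chain
# mass values for the 20 standard amino acids (the tables behind the
# classic pseudo-amino-acid-composition descriptors).
.chou_raw <- local({
  m <- rbind(
    hydrophobicity = c(A =  0.62, C =  0.29, D = -0.90, E = -0.74,
                       F =  1.19, G =  0.48, H = -0.40, I =  1.38,
                       K = -1.50, L =  1.06, M =  0.64, N = -0.78,
                       P =  0.12, Q = -0.85, R = -2.53, S = -0.18,
                       T = -0.05, V =  1.08, W =  0.81, Y =  0.26),
    hydrophilicity = c(A = -0.5,  C = -1.0,  D =  3.0,  E =  3.0,
                       F = -2.5,  G =  0.0,  H = -0.5,  I = -1.8,
                       K =  3.0,  L = -1.8,  M = -1.3,  N =  0.2,
                       P =  0.0,  Q =  0.2,  R =  3.0,  S =  0.3,
                       T = -0.4,  V = -1.5,  W = -3.4,  Y = -2.3),
    side_chain_mass = c(A =  15.0, C =  47.0, D =  59.0, E =  73.0,
                        F =  91.0, G =   1.0, H =  82.0, I =  57.0,
                        K =  73.0, L =  57.0, M =  75.0, N =  58.0,
                        P =  42.0, Q =  72.0, R = 101.0, S =  31.0,
                        T =  45.0, V =  43.0, W = 130.0, Y = 107.0))
  m[, AA20, drop = FALSE]
})

#' Physicochemical index sets for pseudo amino acid composition
#'
#' `sno_indices()` returns an index set: a numeric matrix with one row per
#' physicochemical index and one column per standard amino acid, plus the
#' standardized version used inside the sequence-order correlation factor.
#' The default set is the classic trio behind PC-PseAAC: hydrophobicity,
#' hydrophilicity and side-chain mass. Custom indices (the general
#' descriptor accepts any) can be supplied as a matrix or read from a
#' two-column TSV with `read_index_tsv()`.
#'
#' Standardization centers each index to mean 0 over the 20 amino acids
#' and scales it to unit mean square (population normalisation, divisor
#' 20), so indices on different natural scales contribute comparably to
#' the squared-difference correlation.
#'
#' @param raw numeric matrix (indices x 20 amino acids) of raw values;
#'   columns must cover the 20 standard amino acids.
#' @return An object of class `sno_indices`: list with `raw` and
#'   `standardized` matrices (rows = indices, columns = the 20 residues).
#' @examples
#' idx <- sno_indices()
#' rowMeans(idx$standardized)          # ~0
#' rowMeans(idx$standardized^2)        # 1
#' @export
sno_indices <- function(raw = .chou_raw) {
  raw <- as.matrix(raw)
  if (is.null(colnames(raw)) || !setequal(colnames(raw), AA20))
    stop("index matrix must have one column per standard amino acid")
  raw <- raw[, AA20, drop = FALSE]
  if (is.null(rownames(raw)))
    rownames(raw) <- sprintf("index%d", seq_len(nrow(raw)))
  structure(list(raw = raw, standardized = standardize_indices(raw)),
            class = "sno_indices")
}

#' Standardize physicochemical index rows
#'
#' Each index (row) is centered to zero mean over the 20 amino acids and
#' divided by its population root-mean-square deviation (divisor 20), so
#' the standardized values have mean 0 and mean square 1.
#'
#' @param raw numeric matrix, indices in rows, the 20 amino acids in
#'   columns.
#' @return Matrix of the same shape with standardized values.
#' @export
standardize_indices <- function(raw) {
  raw <- as.matrix(raw)
  t(apply(raw, 1L, function(v) {
    mu <- mean(v)
    rms <- sqrt(mean((v - mu)^2))
    if (rms == 0) stop("degenerate index: zero variance over the 20 amino acids")
    (v - mu) / rms
  }))
}

#' @rdname sno_indices
#' @param path TSV file with columns amino acid, value (one index) or an
#'   amino-acid column followed by one column per index.
#' @export
read_index_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  aa <- toupper(trimws(df[[1L]]))
  if (!setequal(aa, AA20))
    stop("index TSV must list exactly the 20 standard amino acids")
  vals <- as.matrix(df[, -1L, drop = FALSE])
  m <- t(vals)
  colnames(m) <- aa
  sno_indices(m[, AA20, drop = FALSE])
}

#' @export
print.sno_indices <- function(x, ...) {
  cat(sprintf("sno_indices: %d physicochemical index(es) over 20 amino acids\n",
              nrow(x$raw)))
  cat("  ", paste(rownames(x$raw), collapse = ", "), "\n")
  invisible(x)
}
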