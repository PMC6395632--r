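# Training-set-dependent positional profiles and the five encoders built
# on them (BPB, ANBPB, DBPB, IAAPair, PSTAAP).
#
# Center-inclusion conventions reproduce the standard dimensions at
# t = 10: BPB/ANBPB/DBPB/PSTAAP operate on the window with the center
# cysteine removed (20 residues -> 40, 40, 38, 18 features); IAAPair
# operates on the full 21-residue window (20 adjacent + 19 next-nearest
# pair positions -> 39 features).

lev_pairs21 <- function() paste0(rep(AA21, each = 21L), AA21)
lev_triples21 <- function() {
  p <- paste0(rep(AA21, each = 21L), AA21)
  paste0(rep(p, each = 21L), AA21)
}

# Count occurrences of k-tuples (columns of `keys`, one column per tuple
# position) against the level set `lev`; returns nlev x npos counts.
.tuple_counts <- function(keys, lev) {
  npos <- ncol(keys)
  out <- matrix(0L, nrow = length(lev), ncol = npos)
  for (j in seq_len(npos)) {
    idx <- match(keys[, j], lev)
    out[, j] <- tabulate(idx, nbins = length(lev))
  }
  rownames(out) <- lev
  out
}

#' Fit positional residue profiles from a labeled training set
#'
#' Computes, separately for the positive (SNO) and negative classes, the
#' empirical per-position frequencies of single residues, adjacent and
#' next-nearest residue pairs, and adjacent residue triplets over the
#' 21-letter alphabet. These tables are the supervised half of the
#' bi-profile Bayes encoder family; they must be fitted on training data
#' only (refit per fold in cross-validation) to avoid leakage.
#'
#' @param train a labeled [sno_dataset] with at least one window per class.
#' @param smoothing Laplace pseudocount added to every cell (default 0 =
#'   raw empirical frequencies).
#' @return An object of class `sno_profile` holding count tables
#'   (singles, de-centered pairs, full-window adjacent and gap-1 pairs,
#'   de-centered triplets) for each class, the class sizes and `t`.
#' @examples
#' d <- simulate_dataset(20, 20, t = 3, seed = 1)
#' fit_positional_profiles(d)
#' @export
fit_positional_profiles <- function(train, smoothing = 0) {
  if (!inherits(train, "sno_dataset")) stop("train must be an sno_dataset")
  if (any(is.na(train$label))) stop("all windows must be labeled")
  t <- window_t(train)
  n_pos <- sum(train$label == 1L)
  n_neg <- sum(train$label == 0L)
  if (n_pos < 1L || n_neg < 1L)
    stop("training set must contain both classes")
  lev2 <- lev_pairs21()
  lev3 <- lev_triples21()
  fit_class <- function(peptides) {
    M <- peptide_matrix(peptides)           # n x (2t+1)
    D <- M[, -(t + 1L), drop = FALSE]       # center removed, n x 2t
    n <- nrow(M)
    cols <- function(f, npos)
      matrix(vapply(seq_len(npos), f, character(n)), nrow = n)
    n2t <- ncol(D)
    full <- ncol(M)
    list(
      singles = .tuple_counts(D, AA21),
      pairs_dc = .tuple_counts(
        cols(function(j) paste0(D[, j], D[, j + 1L]), n2t - 1L), lev2),
      pairs0 = .tuple_counts(
        cols(function(j) paste0(M[, j], M[, j + 1L]), full - 1L), lev2),
      pairs1 = .tuple_counts(
        cols(function(j) paste0(M[, j], M[, j + 2L]), full - 2L), lev2),
      triples = .tuple_counts(
        cols(function(j) paste0(D[, j], D[, j + 1L], D[, j + 2L]),
             n2t - 2L), lev3))
  }
  structure(list(
    t = t,
    n_pos = n_pos, n_neg = n_neg,
    smoothing = smoothing,
    pos = fit_class(train$peptide[train$label == 1L]),
    neg = fit_class(train$peptide[train$label == 0L])),
    class = "sno_profile")
}

#' @export
print.sno_profile <- function(x, ...) {
  cat(sprintf(
    "sno_profile: t = %d, fitted on %d positive / %d negative windows%s\n",
    x$t, x$n_pos, x$n_neg,
    if (x$smoothing > 0) sprintf(" (Laplace +%g)", x$smoothing) else ""))
  invisible(x)
}

# Probability of observed tuples: counts + s over n + s * nlevels.
.prob <- function(profile, class, table, idx, pos) {
  counts <- profile[[class]][[table]]
  n <- if (class == "pos") profile$n_pos else profile$n_neg
  s <- profile$smoothing
  (counts[cbind(idx, pos)] + s) / (n + s * nrow(counts))
}

.check_window <- function(window, profile) {
  chars <- strsplit(toupper(window), "", fixed = TRUE)[[1L]]
  if (length(chars) != 2L * profile$t + 1L)
    stop(sprintf("window length %d does not match profile t = %d",
                 length(chars), profile$t))
  if (!all(chars %in% AA21)) stop("illegal residue in window")
  chars
}

.offset_labels <- function(t) c(paste0("m", t:1), paste0("p", 1:t))

#' Bi-profile Bayes encoding of a window
#'
#' For each non-center position the encoder emits the empirical
#' probability of the observed residue at that position, first from the
#' positive-class profile then from the negative-class profile, giving a
#' vector of length `2 * 2t` (40 at t = 10).
#'
#' @param window a peptide window string of length `2t + 1`.
#' @param profile an [sno_profile] fitted with
#'   [fit_positional_profiles()].
#' @return Named numeric vector in `[0, 1]`.
#' @export
encode_bpb <- function(window, profile) {
  chars <- .check_window(window, profile)
  d <- chars[-(profile$t + 1L)]
  idx <- match(d, AA21)
  pos <- seq_along(d)
  v <- c(.prob(profile, "pos", "singles", idx, pos),
         .prob(profile, "neg", "singles", idx, pos))
  names(v) <- c(paste0("pos.", .offset_labels(profile$t)),
                paste0("neg.", .offset_labels(profile$t)))
  v
}

# Per-position z-scored (over the 21 letter-frequencies, population sd)
# probability tables pushed through the standard normal CDF.
.anbpb_table <- function(profile, class) {
  counts <- profile[[class]]$singles
  n <- if (class == "pos") profile$n_pos else profile$n_neg
  s <- profile$smoothing
  f <- (counts + s) / (n + s * nrow(counts))
  apply(f, 2L, function(col) {
    mu <- mean(col)
    sd <- sqrt(mean((col - mu)^2))
    if (sd == 0) rep(0.5, length(col)) else stats::pnorm((col - mu) / sd)
  })
}

#' Adapted-normal bi-profile Bayes encoding
#'
#' As [encode_bpb()], but each positional frequency is z-scored against
#' the 21 letter-frequencies at its position within the class and mapped
#' through the standard normal CDF, spreading the typically small raw
#' frequencies over `[0, 1]`. A constant column (zero spread) maps to
#' 0.5.
#'
#' @inheritParams encode_bpb
#' @return Named numeric vector of length `2 * 2t` in `[0, 1]`.
#' @export
encode_anbpb <- function(window, profile) {
  chars <- .check_window(window, profile)
  d <- chars[-(profile$t + 1L)]
  idx <- cbind(match(d, AA21), seq_along(d))
  v <- c(.anbpb_table(profile, "pos")[idx],
         .anbpb_table(profile, "neg")[idx])
  names(v) <- c(paste0("pos.", .offset_labels(profile$t)),
                paste0("neg.", .offset_labels(profile$t)))
  v
}

#' Double bi-profile Bayes encoding (adjacent residue pairs)
#'
#' Positional posterior probabilities of the adjacent residue pairs of
#' the de-centered window (center cysteine removed, so `2t - 1` pair
#' positions), positive-class block then negative-class block; length
#' `2 * (2t - 1)` (38 at t = 10).
#'
#' @inheritParams encode_bpb
#' @return Named numeric vector in `[0, 1]`.
#' @export
encode_dbpb <- function(window, profile) {
  chars <- .check_window(window, profile)
  d <- chars[-(profile$t + 1L)]
  keys <- paste0(d[-length(d)], d[-1L])
  idx <- match(keys, lev_pairs21())
  pos <- seq_along(keys)
  v <- c(.prob(profile, "pos", "pairs_dc", idx, pos),
         .prob(profile, "neg", "pairs_dc", idx, pos))
  names(v) <- c(paste0("pos.pair", pos), paste0("neg.pair", pos))
  v
}

#' Pairwise positional propensity encoding (adjacent + next-nearest)
#'
#' Over the full `2t + 1` window (the center cysteine is kept), emits for
#' each of the `2t` adjacent-pair positions and the `2t - 1` gap-1 pair
#' positions the difference between the positive-class and
#' negative-class posterior probability of the observed pair; length
#' `4t - 1` (39 at t = 10), entries in `[-1, 1]`.
#'
#' @inheritParams encode_bpb
#' @return Named numeric vector in `[-1, 1]`.
#' @export
encode_iaapair <- function(window, profile) {
  chars <- .check_window(window, profile)
  lev2 <- lev_pairs21()
  L <- length(chars)
  k0 <- paste0(chars[-L], chars[-1L])                 # adjacent, 2t
  k1 <- paste0(chars[seq_len(L - 2L)], chars[seq_len(L - 2L) + 2L]) # gap 1
  i0 <- match(k0, lev2); p0 <- seq_along(k0)
  i1 <- match(k1, lev2); p1 <- seq_along(k1)
  v <- c(.prob(profile, "pos", "pairs0", i0, p0) -
           .prob(profile, "neg", "pairs0", i0, p0),
         .prob(profile, "pos", "pairs1", i1, p1) -
           .prob(profile, "neg", "pairs1", i1, p1))
  names(v) <- c(paste0("adj", p0), paste0("gap1.", p1))
  v
}

#' Tri-amino-acid positional propensity encoding
#'
#' Positive-minus-negative posterior probabilities of the adjacent
#' residue triplets of the de-centered window (`2t - 2` triplet
#' positions; 18 at t = 10), entries in `[-1, 1]`.
#'
#' @inheritParams encode_bpb
#' @return Named numeric vector in `[-1, 1]`.
#' @export
encode_pstaap <- function(window, profile) {
  chars <- .check_window(window, profile)
  d <- chars[-(profile$t + 1L)]
  m <- length(d)
  keys <- paste0(d[seq_len(m - 2L)], d[seq_len(m - 2L) + 1L],
                 d[seq_len(m - 2L) + 2L])
  idx <- match(keys, lev_triples21())
  pos <- seq_along(keys)
  v <- .prob(profile, "pos", "triples", idx, pos) -
       .prob(profile, "neg", "triples", idx, pos)
  names(v) <- paste0("tri", pos)
  v
}

#' Serialize positional profiles to JSON
#'
#' Profiles are written as a single JSON document holding `t`, the class
#' sizes, the smoothing constant and the non-zero count cells of every
#' table (counts, not probabilities, so the round trip is exact).
#'
#' @param profile an [sno_profile].
#' @param path output (input) file path.
#' @return `write_profiles` returns `path` invisibly; `read_profiles`
#'   returns the reconstructed `sno_profile`.
#' @export
write_profiles <- function(profile, path) {
  sparsify <- function(m) {
    nz <- which(m != 0L)
    list(nrow = nrow(m), ncol = ncol(m),
         i = as.integer((nz - 1L) %% nrow(m) + 1L),
         j = as.integer((nz - 1L) %/% nrow(m) + 1L),
         x = as.integer(m[nz]))
  }
  doc <- list(
    format = "sno_profile", version = 1L,
    t = profile$t, n_pos = profile$n_pos, n_neg = profile$n_neg,
    smoothing = profile$smoothing,
    alphabet = AA21,
    pos = lapply(profile$pos, sparsify),
    neg = lapply(profile$neg, sparsify))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "sno_profile"))
    stop("not a serialized sno_profile: ", path)
  lev2 <- lev_pairs21()
  lev3 <- lev_triples21()
  levels_for <- list(singles = AA21, pairs_dc = lev2, pairs0 = lev2,
                     pairs1 = lev2, triples = lev3)
  densify <- function(s, lev) {
    m <- matrix(0L, nrow = s$nrow, ncol = s$ncol)
    if (length(s$i)) m[cbind(s$i, s$j)] <- as.integer(s$x)
    rownames(m) <- lev
    m
  }
  rebuild <- function(cls)
    Map(densify, cls[names(levels_for)], levels_for)
  structure(list(
    t = as.integer(doc$t),
    n_pos = as.integer(doc$n_pos), n_neg = as.integer(doc$n_neg),
    smoothing = doc$smoothing,
    pos = rebuild(doc$pos),
    neg = rebuild(doc$neg)),
    class = "sno_profile")
}
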