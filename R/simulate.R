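# Seeded generators for synthetic proteins and labeled window datasets
# with planted position-specific residue enrichment. These emulate the
# structure the profile encoders and information gain assume: a fixed
# background residue distribution at every non-center position, with one
# or more signal residues enriched in positives relative to negatives.

#' Motif specification for the window simulator
#'
#' A motif is a set of positional signals: at window offset `offset`
#' (relative to the center cysteine, never 0), residue `residue` is
#' planted with probability `p_pos` in positive windows and `p_neg` in
#' negative ones. All other positions (and the signal position when the
#' plant does not fire) are drawn from `background`.
#'
#' The default motif is a single lysine enriched immediately upstream of
#' the cysteine: K at offset -1 with probability 0.8 in positives and
#' 0.05 in negatives over a uniform background.
#'
#' @param signals data frame with columns `offset`, `residue`, `p_pos`,
#'   `p_neg`.
#' @param background named probability vector over the 20 standard amino
#'   acids (default uniform); must sum to 1.
#' @return Object of class `motif_spec`.
#' @examples
#' motif_spec()   # the default planted-K motif
#' @export
motif_spec <- function(signals = data.frame(offset = -1L, residue = "K",
                                            p_pos = 0.8, p_neg = 0.05),
                       background = NULL) {
  if (is.null(background))
    background <- stats::setNames(rep(1 / 20, 20), AA20)
  if (!setequal(names(background), AA20))
    stop("background must cover exactly the 20 standard amino acids")
  background <- background[AA20]
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  stopifnot(all(c("offset", "residue", "p_pos", "p_neg") %in%
                  names(signals)))
  if (any(signals$offset == 0L))
    stop("signal offset 0 is the center cysteine")
  if (any(signals$p_pos < 0 | signals$p_pos > 1 |
          signals$p_neg < 0 | signals$p_neg > 1))
    stop("signal probabilities must lie in [0, 1]")
  if (!all(signals$residue %in% AA20))
    stop("signal residues must be standard amino acids")
  structure(list(signals = signals, background = background),
            class = "motif_spec")
}

#' Simulate a labeled cysteine-window dataset
#'
#' Generates `n_pos` positive and `n_neg` negative windows of length
#' `2t + 1` with a `C` at the center. Every non-center position is drawn
#' from the motif background, then each signal position is overwritten
#' by its signal residue with the class-specific probability. The result
#' is deterministic given `seed`.
#'
#' @param n_pos,n_neg number of positive / negative windows (>= 1).
#' @param t window half-width.
#' @param motif a [motif_spec()]; signals must fit inside the window.
#' @param seed integer seed.
#' @return A labeled [sno_dataset] with positives first.
#' @examples
#' d <- simulate_dataset(5, 5, t = 10, seed = 1)
#' d$peptide[1]
#' @export
simulate_dataset <- function(n_pos, n_neg, t = 10L, motif = motif_spec(),
                             seed = 1L) {
  if (n_pos < 1L || n_neg < 1L) stop("counts must be >= 1")
  if (!inherits(motif, "motif_spec")) motif <- do.call(motif_spec, motif)
  t <- as.integer(t)
  if (any(abs(motif$signals$offset) > t))
    stop("signal offset outside the window")
  set.seed(as.integer(seed))
  L <- 2L * t + 1L
  gen_class <- function(n, pcol) {
    M <- matrix(sample(AA20, n * L, replace = TRUE,
                       prob = motif$background),
                nrow = n, ncol = L)
    M[, t + 1L] <- "C"
    for (s in seq_len(nrow(motif$signals))) {
      sig <- motif$signals[s, ]
      col <- t + 1L + sig$offset
      fire <- stats::runif(n) < sig[[pcol]]
      M[fire, col] <- sig$residue
    }
    apply(M, 1L, paste, collapse = "")
  }
  pep_pos <- gen_class(n_pos, "p_pos")
  pep_neg <- gen_class(n_neg, "p_neg")
  sno_dataset(c(pep_pos, pep_neg),
              label = c(rep(1L, n_pos), rep(0L, n_neg)))
}

#' Simulate random protein sequences
#'
#' Random proteins with a controllable expected cysteine fraction; the
#' non-cysteine positions are uniform over the other 19 standard
#' residues. Used to exercise window extraction end-to-end.
#'
#' @param n number of proteins.
#' @param length protein length in residues.
#' @param cys_rate expected fraction of cysteines, in `[0, 1]`.
#' @param seed integer seed.
#' @return Named character vector of sequences (`prot1 ... protn`),
#'   writable with [write_fasta()].
#' @examples
#' simulate_proteins(2, 30, cys_rate = 0.1, seed = 7)
#' @export
simulate_proteins <- function(n, length, cys_rate = 0.05, seed = 1L) {
  if (length < 1L) stop("length must be >= 1")
  if (cys_rate < 0 || cys_rate > 1) stop("cys_rate must lie in [0, 1]")
  set.seed(as.integer(seed))
  others <- setdiff(AA20, "C")
  seqs <- vapply(seq_len(n), function(i) {
    is_c <- stats::runif(length) < cys_rate
    chars <- ifelse(is_c, "C", sample(others, length, replace = TRUE))
    paste(chars, collapse = "")
  }, character(1L))
  stats::setNames(seqs, paste0("prot", seq_len(n)))
}
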