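# Composition encoders: pseudo amino acid composition (parallel
# correlation form and its general multi-index form) and basic kmer
# frequencies.
#
# The dummy residue X has no physicochemical values and no slot in the
# 20-letter composition alphabet, so it is excluded throughout: residue
# pairs containing X are skipped in the correlation factors (with the
# denominator reduced to the number of evaluated pairs), and X never
# enters the numerator or denominator of a frequency.

#' Sequence-order correlation between two residues
#'
#' The squared-difference correlation function at the heart of pseudo
#' amino acid composition: the mean over physicochemical indices of the
#' squared difference of standardized index values of the two residues.
#' Mode `"pcpseaac3"` fixes the indices to the classic hydrophobicity /
#' hydrophilicity / side-chain-mass trio; mode `"general"` averages over
#' however many indices the set carries.
#'
#' @param r_i,r_j single standard amino-acid letters.
#' @param indices an [sno_indices] set.
#' @param mode `"pcpseaac3"` (first three indices) or `"general"` (all).
#' @return Non-negative number; 0 when `r_i == r_j`.
#' @examples
#' theta_correlation("A", "A")        # 0
#' theta_correlation("K", "R")
#' @export
theta_correlation <- function(r_i, r_j, indices = sno_indices(),
                              mode = c("pcpseaac3", "general")) {
  mode <- match.arg(mode)
  H <- indices$standardized
  if (mode == "pcpseaac3") {
    if (nrow(H) < 3L) stop("pcpseaac3 mode needs three indices")
    H <- H[1:3, , drop = FALSE]
  }
  if (!r_i %in% AA20 || !r_j %in% AA20)
    stop("theta_correlation is defined for standard residues only")
  mean((H[, r_i] - H[, r_j])^2)
}

# Tier correlation factors Theta_1..Theta_lam for a residue vector.
# Pairs containing X are skipped; each tier's mean is over the evaluated
# pairs only. Returns NA for a tier with no evaluable pair.
tier_thetas <- function(chars, lam, H) {
  L <- length(chars)
  vapply(seq_len(lam), function(j) {
    a <- chars[seq_len(L - j)]
    b <- chars[seq_len(L - j) + j]
    keep <- a != "X" & b != "X"
    if (!any(keep)) return(NA_real_)
    d <- H[, a[keep], drop = FALSE] - H[, b[keep], drop = FALSE]
    mean(colMeans(d^2))
  }, numeric(1L))
}

#' Pseudo amino acid composition of a peptide
#'
#' Encodes a peptide as 20 normalized amino-acid frequencies plus
#' `lam` sequence-order correlation terms, all sharing the common
#' denominator \eqn{\sum f_i + w \sum \Theta_j}, so the vector sums to 1.
#' With `mode = "pcpseaac3"` the correlation uses the classic three
#' indices; `mode = "general"` averages over all indices in `indices`.
#'
#' Occurrences of the dummy residue `X` are excluded from the frequencies,
#' and residue pairs containing `X` are skipped in the correlation tiers.
#'
#' @param sequence peptide string (typically a 21-mer window).
#' @param lam number of correlation tiers (\eqn{\lambda \ge 0}); must be
#'   smaller than the number of non-`X` residues.
#' @param w weight of the correlation block, in `[0, 1]`.
#' @param indices an [sno_indices] set.
#' @param mode `"pcpseaac3"` or `"general"`.
#' @return Named numeric vector of length `20 + lam` summing to 1; names
#'   `f.A ... f.Y`, `theta.1 ... theta.<lam>` (prefixed `g.` in general
#'   mode).
#' @examples
#' v <- encode_pc_pseaac("AAAAAAAAAACAAAAAAAAAA", lam = 5, w = 0.5)
#' sum(v)   # 1
#' @export
encode_pc_pseaac <- function(sequence, lam = 5L, w = 0.5,
                             indices = sno_indices(),
                             mode = c("pcpseaac3", "general")) {
  mode <- match.arg(mode)
  lam <- as.integer(lam)
  if (lam < 0L) stop("lam must be >= 0")
  if (w < 0 || w > 1) stop("w must lie in [0, 1]")
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  if (!all(chars %in% AA21)) stop("illegal residue in sequence")
  eff <- sum(chars != "X")
  if (eff == 0L) stop("sequence contains no standard residue")
  if (lam >= eff)
    stop(sprintf("lam (%d) must be smaller than the effective length (%d)",
                 lam, eff))
  H <- indices$standardized
  if (mode == "pcpseaac3") {
    if (nrow(H) < 3L) stop("pcpseaac3 mode needs three indices")
    H <- H[1:3, , drop = FALSE]
  }
  counts <- table(factor(chars[chars != "X"], levels = AA20))
  f <- as.numeric(counts) / eff            # normalized frequencies, sum 1
  th <- if (lam > 0L) tier_thetas(chars, lam, H) else numeric()
  th[is.na(th)] <- 0
  denom <- sum(f) + w * sum(th)
  v <- c(f / denom, w * th / denom)
  prefix <- if (mode == "general") "g." else ""
  names(v) <- c(paste0(prefix, "f.", AA20),
                if (lam > 0L) paste0(prefix, "theta.", seq_len(lam)))
  v
}

#' kmer composition of a peptide
#'
#' Occurrence frequencies of the `20^k` length-`k` substrings over the
#' standard amino-acid alphabet, normalized by the number of `X`-free
#' k-mers so the vector sums to 1.
#'
#' @param sequence peptide string.
#' @param k substring length, 1 or 2.
#' @return Named numeric vector of length `20^k` summing to 1.
#' @examples
#' encode_kmer("ACAC", k = 2)[c("AC", "CA")]   # 2/3, 1/3
#' @export
encode_kmer <- function(sequence, k = 1L) {
  k <- as.integer(k)
  if (!k %in% c(1L, 2L)) stop("k must be 1 or 2")
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  if (!all(chars %in% AA21)) stop("illegal residue in sequence")
  L <- length(chars)
  if (L < k) stop("sequence shorter than k")
  kmers <- if (k == 1L) chars
           else paste0(chars[-L], chars[-1L])
  keep <- !grepl("X", kmers, fixed = TRUE)
  if (!any(keep)) stop("no X-free k-mer in sequence")
  lev <- if (k == 1L) AA20
         else paste0(rep(AA20, each = 20L), AA20)
  counts <- table(factor(kmers[keep], levels = lev))
  v <- as.numeric(counts) / sum(keep)
  names(v) <- lev
  v
}
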