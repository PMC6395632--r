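# Assembly of per-window encodings into a block-structured feature matrix.

# Canonical encoder order; names are the user-facing encoder identifiers.
ENCODERS <- c("pcpseaac", "kmer1", "kmer2", "pcpseaacg",
              "anbpb", "dbpb", "bpb", "iaapair", "pstaap")

# Which encoders need fitted positional profiles; the remainder depend
# only on the window itself (and so never on a CV fold).
PROFILE_ENCODERS <- c("anbpb", "dbpb", "bpb", "iaapair", "pstaap")
COMPOSITION_ENCODERS <- c("pcpseaac", "kmer1", "kmer2", "pcpseaacg")

#' Encode a window dataset into a feature matrix
#'
#' Applies any subset of the nine sequence encoders to every window of a
#' dataset and binds the results column-wise into one numeric matrix.
#' Composition encoders (`pcpseaac`, `kmer1`, `kmer2`, `pcpseaacg`)
#' depend only on the window itself; the profile encoders (`anbpb`,
#' `dbpb`, `bpb`, `iaapair`, `pstaap`) additionally require positional
#' profiles fitted on training data, passed via `profile`.
#'
#' With all nine encoders at t = 10 and `lam = 5` the matrix has
#' 25 + 20 + 400 + 25 + 40 + 38 + 40 + 39 + 18 = 645 columns.
#'
#' @param dataset an [sno_dataset] (labels not required) or character
#'   vector of equal-length windows.
#' @param encoders character vector of encoder names, in the order the
#'   blocks should appear; defaults to all nine.
#' @param profile an [sno_profile]; required iff a profile encoder is
#'   requested.
#' @param lam,w pseudo amino acid composition parameters.
#' @param indices physicochemical [sno_indices] for the composition
#'   encoders.
#' @return Numeric matrix (windows x features). Column names are
#'   `<encoder>.<feature>`; attribute `blocks` maps each encoder to its
#'   column range (a named list of integer vectors).
#' @examples
#' d <- simulate_dataset(10, 10, t = 10, seed = 1)
#' pr <- fit_positional_profiles(d)
#' X <- encode_features(d, profile = pr)
#' dim(X)                     # 20 x 645
#' names(attr(X, "blocks"))
#' @export
encode_features <- function(dataset, encoders = ENCODERS, profile = NULL,
                            lam = 5L, w = 0.5, indices = sno_indices()) {
  peptides <- if (inherits(dataset, "sno_dataset")) dataset$peptide
              else as.character(dataset)
  unknown <- setdiff(encoders, ENCODERS)
  if (length(unknown))
    stop("unknown encoder(s): ", paste(unknown, collapse = ", "),
         " (available: ", paste(ENCODERS, collapse = ", "), ")")
  if (any(encoders %in% PROFILE_ENCODERS) && is.null(profile))
    stop("profile encoders requested but no fitted profile supplied")
  one <- function(enc, pep) {
    switch(enc,
      pcpseaac  = encode_pc_pseaac(pep, lam = lam, w = w, indices = indices,
                                   mode = "pcpseaac3"),
      pcpseaacg = encode_pc_pseaac(pep, lam = lam, w = w, indices = indices,
                                   mode = "general"),
      kmer1     = encode_kmer(pep, k = 1L),
      kmer2     = encode_kmer(pep, k = 2L),
      bpb       = encode_bpb(pep, profile),
      anbpb     = encode_anbpb(pep, profile),
      dbpb      = encode_dbpb(pep, profile),
      iaapair   = encode_iaapair(pep, profile),
      pstaap    = encode_pstaap(pep, profile))
  }
  blocks <- list()
  mats <- vector("list", length(encoders))
  at <- 0L
  for (e in seq_along(encoders)) {
    enc <- encoders[e]
    proto <- one(enc, peptides[1L])
    m <- matrix(vapply(peptides, function(p) one(enc, p),
                       numeric(length(proto))),
                nrow = length(peptides), byrow = TRUE)
    colnames(m) <- paste0(enc, ".", names(proto))
    mats[[e]] <- m
    blocks[[enc]] <- at + seq_len(ncol(m))
    at <- at + ncol(m)
  }
  X <- do.call(cbind, mats)
  rownames(X) <- NULL
  structure(X, blocks = blocks)
}

#' Restrict a feature matrix to named features or block columns
#'
#' Keeps the given feature columns (by name or index) and rewrites the
#' block map accordingly.
#'
#' @param X matrix from [encode_features()].
#' @param features character (column names) or integer indices.
#' @return The column-subset matrix with an updated `blocks` attribute.
#' @export
subset_features <- function(X, features) {
  idx <- if (is.character(features)) match(features, colnames(X))
         else as.integer(features)
  if (anyNA(idx)) stop("unknown feature name(s)")
  blocks <- attr(X, "blocks")
  Xs <- X[, idx, drop = FALSE]
  newblocks <- lapply(blocks, function(b) which(idx %in% b))
  structure(Xs, blocks = newblocks[vapply(newblocks, length, 1L) > 0L])
}
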