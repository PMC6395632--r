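#' @keywords internal
"_PACKAGE"

# 20 standard amino acids, alphabetical one-letter order.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Window alphabet: the 20 standard residues plus the dummy residue X used
# to pad windows that run past a protein terminus.
AA21 <- c(AA20, "X")

# Letters commonly found in real FASTA that carry no physicochemical model
# here; they are folded into X on input.
NONSTANDARD <- c("B", "Z", "U", "O", "J", "*")

#' Amino-acid alphabets used by the package
#'
#' `sno_alphabet()` returns the residue alphabets the encoders operate on:
#' the 20 standard amino acids and the 21-letter window alphabet that adds
#' the dummy padding residue `X`.
#'
#' @param include_x logical; include the dummy residue `X`.
#' @return Character vector of one-letter residue codes.
#' @examples
#' sno_alphabet()            # 21 letters
#' sno_alphabet(FALSE)       # the 20 standard amino acids
#' @export
sno_alphabet <- function(include_x = TRUE) {
  if (include_x) AA21 else AA20
}

# Split peptide strings into an N x L character matrix. All strings must
# have equal nchar (callers validate first).
peptide_matrix <- function(peptides) {
  n <- length(peptides)
  L <- nchar(peptides[1L])
  matrix(unlist(strsplit(peptides, "", fixed = TRUE), use.names = FALSE),
         nrow = n, ncol = L, byrow = TRUE)
}

# Map non-standard letters to X, warning once per call with the set seen.
sanitize_residues <- function(x, context = "sequence") {
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), AA21)
  if (length(bad)) {
    warning(sprintf("mapping non-standard letter(s) %s to X in %s",
                    paste(bad, collapse = ", "), context), call. = FALSE)
    chars[chars %in% bad] <- "X"
  }
  paste(chars, collapse = "")
}
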