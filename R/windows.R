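# Cysteine-centered peptide windows and labeled window datasets.
#
# A window is the (2t+1)-residue neighbourhood of a cysteine: positions
# -t..-1 upstream, the cysteine at offset 0, +1..+t downstream. Flanks
# that run past a protein terminus are padded with the dummy residue X.

#' Construct a labeled peptide-window dataset
#'
#' Bundles equal-length cysteine-centered peptide windows with binary
#' labels (1 = S-nitrosylated, 0 = not) into the container the encoders,
#' feature-selection and evaluation functions operate on.
#'
#' @param peptide character vector of windows, all the same odd length
#'   \eqn{2t+1} over the 21-letter alphabet (20 amino acids + dummy `X`).
#' @param label integer/numeric/logical vector of 0/1 labels, recycled if
#'   scalar; may be `NULL` for unlabeled windows (prediction input).
#' @param source_id optional protein accessions, one per window.
#' @param site_position optional 1-based position of the center cysteine in
#'   the source protein.
#' @param strict_center logical; require the center residue to be `C`.
#' @return An object of class `sno_dataset`: a data frame with columns
#'   `peptide`, `label` (and optionally `source_id`, `site_position`) and
#'   attribute `t`, the window half-width.
#' @examples
#' d <- sno_dataset(c("AAAAAAAAAACAAAAAAAAAA", "DDDDDDDDDDCDDDDDDDDDD"),
#'                  label = c(1, 0))
#' window_t(d)
#' @export
sno_dataset <- function(peptide, label = NULL, source_id = NULL,
                        site_position = NULL, strict_center = TRUE) {
  peptide <- toupper(as.character(peptide))
  if (!length(peptide)) stop("no peptides supplied")
  lens <- nchar(peptide)
  if (length(unique(lens)) != 1L) {
    bad <- which(lens != lens[1L])[1L]
    stop(sprintf("inconsistent window lengths: row %d has %d, expected %d",
                 bad, lens[bad], lens[1L]))
  }
  L <- lens[1L]
  if (L %% 2L == 0L) stop("window length must be odd (2t+1)")
  t <- (L - 1L) %/% 2L
  for (i in seq_along(peptide)) {
    chk <- validate_window(peptide[i], strict_center = strict_center)
    if (!chk$ok)
      stop(sprintf("row %d: %s", i, paste(chk$problems, collapse = "; ")))
  }
  df <- data.frame(peptide = peptide, stringsAsFactors = FALSE)
  if (!is.null(label)) {
    label <- as.integer(label)
    if (length(label) == 1L) label <- rep(label, length(peptide))
    if (length(label) != length(peptide))
      stop("label length does not match number of peptides")
    if (any(is.na(label)) || !all(label %in% c(0L, 1L)))
      stop("labels must be binary 0/1")
    df$label <- label
  } else {
    df$label <- NA_integer_
  }
  if (!is.null(source_id)) df$source_id <- as.character(source_id)
  if (!is.null(site_position)) df$site_position <- as.integer(site_position)
  structure(df, t = t, class = c("sno_dataset", "data.frame"))
}

#' @rdname sno_dataset
#' @param x an `sno_dataset`.
#' @export
window_t <- function(x) {
  t <- attr(x, "t", exact = TRUE)
  if (is.null(t)) stop("not an sno_dataset: missing half-width attribute")
  t
}

#' @export
print.sno_dataset <- function(x, ...) {
  n <- nrow(x)
  t <- window_t(x)
  lab <- x$label
  cat(sprintf("sno_dataset: %d windows of length %d (t = %d)\n",
              n, 2L * t + 1L, t))
  if (all(is.na(lab))) {
    cat("  unlabeled\n")
  } else {
    cat(sprintf("  %d positive (SNO), %d negative\n",
                sum(lab == 1L), sum(lab == 0L)))
  }
  invisible(x)
}

#' Validate a peptide window
#'
#' Checks the window invariants: odd length, all characters in the
#' 21-letter alphabet and (in strict mode) a cysteine at the center.
#' Returns diagnostics instead of erroring so callers can report all
#' violations at once.
#'
#' @param window a single peptide string.
#' @param strict_center logical; require the center residue to be `C`.
#' @return A list with `ok` (logical) and `problems` (character vector of
#'   human-readable violations, empty when `ok`).
#' @examples
#' validate_window("XXXXXXXXXXCXXXXXXXXXX")$ok
#' validate_window("AAAAAAAAAAAAAAAAAAAAA")$problems
#' @export
validate_window <- function(window, strict_center = TRUE) {
  problems <- character()
  if (length(window) != 1L || !is.character(window)) {
    return(list(ok = FALSE, problems = "window must be a single string"))
  }
  L <- nchar(window)
  if (L %% 2L == 0L)
    problems <- c(problems, sprintf("length %d is even; expected 2t+1", L))
  chars <- strsplit(window, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), AA21)
  if (length(bad))
    problems <- c(problems,
                  sprintf("illegal residue(s): %s", paste(bad, collapse = ", ")))
  if (strict_center && L %% 2L == 1L) {
    center <- chars[(L + 1L) %/% 2L]
    if (!identical(center, "C"))
      problems <- c(problems, sprintf("center residue is '%s', not C", center))
  }
  list(ok = length(problems) == 0L, problems = problems)
}

#' Extract cysteine-centered windows from a protein sequence
#'
#' Returns one window per cysteine in the protein: the cysteine at the
#' center flanked by `t` residues on each side, padded with the dummy
#' residue `X` where the protein ends. Non-standard letters (B, Z, U, O,
#' J, *) are mapped to `X` with a warning.
#'
#' @param protein_sequence a single protein sequence string.
#' @param t window half-width (positive integer); the field-standard
#'   choice for SNO-site work is `t = 10`, giving 21-mers.
#' @param id optional protein accession recorded in the result.
#' @return An unlabeled `sno_dataset` with one row per cysteine, in order
#'   of position, carrying `source_id` and 1-based `site_position`; or
#'   `NULL` when the protein contains no cysteine.
#' @examples
#' extract_windows("MKACDEFGHC", t = 3)
#' @export
extract_windows <- function(protein_sequence, t = 10L, id = NULL) {
  if (length(protein_sequence) != 1L || !nzchar(protein_sequence))
    stop("protein_sequence must be a single non-empty string")
  t <- as.integer(t)
  if (is.na(t) || t < 1L) stop("t must be a positive integer")
  seqc <- sanitize_residues(toupper(protein_sequence),
                            context = if (is.null(id)) "protein" else id)
  chars <- strsplit(seqc, "", fixed = TRUE)[[1L]]
  pos <- which(chars == "C")
  if (!length(pos)) return(NULL)
  padded <- c(rep("X", t), chars, rep("X", t))
  windows <- vapply(pos, function(p) {
    paste(padded[p:(p + 2L * t)], collapse = "")
  }, character(1L))
  sno_dataset(windows,
              label = NULL,
              source_id = rep(if (is.null(id)) NA_character_ else id,
                              length(pos)),
              site_position = pos)
}

#' Read and write labeled peptide-window datasets
#'
#' The canonical on-disk format is two-column TSV (`peptide`, `label`,
#' header optional). A FASTA dialect is also read and written, with the
#' label carried in the header as `|label=0` / `|label=1`.
#'
#' @param path file path.
#' @param format `"tsv"` or `"fasta-pair"`; `load_dataset` guesses from
#'   the extension when missing.
#' @param strict_center logical; require a center cysteine in each window.
#' @param quiet logical; suppress the per-class count message.
#' @return `load_dataset` returns an `sno_dataset`; `write_dataset`
#'   returns `path` invisibly.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' d <- sno_dataset(c("AACAA", "DDCDD"), label = c(1, 0))
#' write_dataset(d, tf)
#' load_dataset(tf)
#' @export
load_dataset <- function(path, format = c("auto", "tsv", "fasta-pair"),
                         strict_center = TRUE, quiet = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|faa)$", path, ignore.case = TRUE))
      "fasta-pair" else "tsv"
  }
  if (format == "tsv") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("empty dataset file: ", path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nc <- lengths(parts)
    if (any(nc < 2L))
      stop(sprintf("row %d: expected 2 tab-separated columns",
                   which(nc < 2L)[1L]))
    pep <- vapply(parts, `[[`, character(1L), 1L)
    lab <- vapply(parts, `[[`, character(1L), 2L)
    # optional header
    if (tolower(pep[1L]) %in% c("peptide", "window", "sequence")) {
      pep <- pep[-1L]; lab <- lab[-1L]
    }
    lab <- trimws(lab)
    if (!all(lab %in% c("0", "1"))) {
      bad <- which(!lab %in% c("0", "1"))[1L]
      stop(sprintf("row %d: unknown label token '%s'", bad, lab[bad]))
    }
    ds <- sno_dataset(pep, label = as.integer(lab),
                      strict_center = strict_center)
  } else {
    recs <- read_fasta(path)
    lab <- regmatches(names(recs), regexpr("label=[01]", names(recs)))
    if (length(lab) != length(recs))
      stop("every FASTA header must carry |label=0 or |label=1")
    ds <- sno_dataset(unname(recs),
                      label = as.integer(sub("label=", "", lab)),
                      source_id = sub("\\|.*$", "", names(recs)),
                      strict_center = strict_center)
  }
  if (!quiet)
    message(sprintf("loaded %d windows (t = %d): %d positive, %d negative",
                    nrow(ds), window_t(ds),
                    sum(ds$label == 1L), sum(ds$label == 0L)))
  ds
}

#' @rdname load_dataset
#' @param dataset an `sno_dataset`.
#' @export
write_dataset <- function(dataset, path, format = c("tsv", "fasta-pair")) {
  format <- match.arg(format)
  if (format == "tsv") {
    writeLines(paste(dataset$peptide, dataset$label, sep = "\t"), path)
  } else {
    ids <- if (!is.null(dataset$source_id)) dataset$source_id
           else sprintf("win%d", seq_len(nrow(dataset)))
    headers <- sprintf(">%s|label=%d", ids, dataset$label)
    writeLines(rbind(headers, dataset$peptide), path)
  }
  invisible(path)
}

#' Read and write plain FASTA
#'
#' Minimal multi-record FASTA I/O (wrapped lines supported) shared by the
#' window extractor and the protein simulator.
#'
#' @param path file path.
#' @return `read_fasta` returns a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!length(lines) || !hdr[1L]) stop("not a FASTA file: ", path)
  idx <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste, character(1L),
                 collapse = "")
  names(seqs) <- sub("^>", "", lines[hdr])[as.integer(names(seqs))]
  seqs
}

#' @rdname read_fasta
#' @param sequences named character vector of sequences.
#' @param width line-wrap width.
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  out <- character()
  for (i in seq_along(sequences)) {
    s <- sequences[[i]]
    starts <- seq(1L, nchar(s), by = width)
    out <- c(out, paste0(">", names(sequences)[i]),
             substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }
  writeLines(out, path)
  invisible(path)
}
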