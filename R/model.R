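# Single-call model interface: sno_fit() fits the complete pipeline on a
# labeled window dataset and returns a classed object with the usual
# predict / print / summary methods.

#' Fit an S-nitrosylation site predictor
#'
#' Fits the full prediction pipeline -- positional profiles, the chosen
#' sequence encoders, optional information-gain or MRMD feature
#' selection, per-feature standardization and a binary classifier -- on
#' a labeled cysteine-window dataset.
#'
#' @param dataset a labeled [sno_dataset] (see [load_dataset()],
#'   [extract_windows()], [simulate_dataset()]).
#' @param config an [sno_config()]; individual arguments below override
#'   its fields for convenience.
#' @param ... passed to [sno_config()] when `config` is missing.
#' @return Object of class `sno_model` with components `config`,
#'   `profile`, `features` (the retained feature names), the fitted
#'   classifier state, and training metadata.
#' @seealso [predict.sno_model()], [cross_validate()]
#' @examples
#' d <- simulate_dataset(60, 60, t = 10, seed = 1)
#' m <- sno_fit(d, encoders = c("bpb", "kmer1"), seed = 1)
#' p <- predict(m, d)
#' head(p$label)
#' @export
sno_fit <- function(dataset, config = NULL, ...) {
  if (is.null(config)) config <- sno_config(...)
  if (!inherits(config, "sno_config")) stop("config must be an sno_config")
  if (any(is.na(dataset$label))) stop("dataset must be fully labeled")
  set.seed(config$seed)
  fitted <- fit_pipeline(dataset, config)
  structure(list(config = config,
                 profile = fitted$profile,
                 features = fitted$features,
                 scaler = fitted$scaler,
                 state = fitted$state,
                 t = window_t(dataset),
                 n_train = nrow(dataset),
                 n_pos = sum(dataset$label == 1L),
                 n_neg = sum(dataset$label == 0L)),
            class = "sno_model")
}

#' Predict S-nitrosylation for new windows
#'
#' @param object an [sno_fit()] model.
#' @param newdata an [sno_dataset], character vector of windows of the
#'   model's length, or a protein sequence string longer than one window
#'   (then windows are extracted around every cysteine first).
#' @param ... unused.
#' @return Data frame with columns `peptide`, `score` (larger = more
#'   SNO-like), `label` (0/1) and, when windows were extracted from a
#'   protein, `site_position`.
#' @export
predict.sno_model <- function(object, newdata, ...) {
  site <- NULL
  if (is.character(newdata)) {
    if (length(newdata) == 1L &&
        nchar(newdata) > 2L * object$t + 1L) {
      ds <- extract_windows(newdata, t = object$t)
      if (is.null(ds)) return(data.frame(peptide = character(),
                                         score = numeric(),
                                         label = integer()))
      site <- ds$site_position
      newdata <- ds
    } else {
      newdata <- sno_dataset(newdata)
    }
  }
  if (window_t(newdata) != object$t)
    stop("window half-width does not match the fitted model")
  out <- predict_pipeline(list(config = object$config,
                               profile = object$profile,
                               features = object$features,
                               scaler = object$scaler,
                               state = object$state),
                          newdata)
  res <- data.frame(peptide = newdata$peptide, score = out$score,
                    label = out$label, stringsAsFactors = FALSE)
  if (!is.null(site)) res$site_position <- site
  res
}

#' @export
print.sno_model <- function(x, ...) {
  cat("sno_model: S-nitrosylation site predictor\n")
  cat(sprintf("  trained on %d windows (%d SNO / %d non-SNO), t = %d\n",
              x$n_train, x$n_pos, x$n_neg, x$t))
  cat(sprintf("  encoders: %s\n", paste(x$config$encoders, collapse = ", ")))
  cat(sprintf("  features: %d retained (%s selection)\n",
              length(x$features),
              if (x$config$selection == "none") "no"
              else x$config$selection))
  cat(sprintf("  classifier: %s\n", x$config$classifier$name))
  invisible(x)
}

#' @export
summary.sno_model <- function(object, ...) {
  blocks <- table(sub("\\..*$", "", object$features))
  cat("sno_model summary\n")
  print(object)
  cat("  retained features per encoder block:\n")
  for (b in names(blocks))
    cat(sprintf("    %-10s %d\n", b, blocks[[b]]))
  invisible(object)
}
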