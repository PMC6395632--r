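# Incremental feature selection: walk down a feature ranking, evaluate
# the top-d subset at each candidate dimension, keep the dimension with
# the best accuracy.

#' Incremental feature selection along a ranking
#'
#' Evaluates the top-`d` features of a ranking for each candidate
#' dimension `d` and records Sn/Sp/Acc/MCC; the selected dimension is
#' the one maximizing accuracy, ties resolved toward the smallest
#' dimension.
#'
#' @param ranked an `sno_ranking` (from [rank_features_ig()] or
#'   [mrmd_rank()]).
#' @param evaluator function taking a dimension `d` and returning an
#'   [sno_metrics][compute_metrics] (or any list with `sn`, `sp`, `acc`,
#'   `mcc`); typically a closure running cross-validation on the top-`d`
#'   feature columns. Must be deterministic given its own seed.
#' @param dims integer vector of dimensions to test (default: every
#'   dimension 1..length(ranking)) or a single step size via `step`.
#' @param step when `dims` is missing, evaluate `seq(step, D, by
#'   = step)` (plus `D` itself).
#' @return Object of class `sno_selection`: data frame `trace` with
#'   columns `dim`, `sn`, `sp`, `acc`, `mcc`; `best_dim`; and
#'   `features`, the selected top-`best_dim` feature names.
#' @examples
#' rk <- structure(list(order = paste0("f", 1:20), scores = 20:1,
#'                      method = "ig"), class = "sno_ranking")
#' ev <- function(d) list(sn = 0, sp = 0, acc = 1 - abs(d - 7) / 100,
#'                        mcc = 0)
#' incremental_selection(rk, ev)$best_dim   # 7
#' @export
incremental_selection <- function(ranked, evaluator, dims = NULL,
                                  step = 1L) {
  D <- length(ranked$order)
  if (is.null(dims)) {
    dims <- unique(c(seq(step, D, by = step), D))
  }
  dims <- sort(unique(as.integer(dims)))
  if (!length(dims)) stop("no candidate dimensions supplied")
  if (any(dims < 1L | dims > D))
    stop("candidate dimensions must lie in 1..", D)
  rows <- lapply(dims, function(d) {
    m <- evaluator(d)
    data.frame(dim = d, sn = m$sn, sp = m$sp, acc = m$acc, mcc = m$mcc)
  })
  trace <- do.call(rbind, rows)
  best_dim <- trace$dim[which.max(trace$acc)]  # which.max: first = smallest d
  structure(list(trace = trace,
                 best_dim = best_dim,
                 features = ranked$order[seq_len(best_dim)],
                 method = ranked$method),
            class = "sno_selection")
}

#' @export
print.sno_selection <- function(x, ...) {
  cat(sprintf("incremental selection (%s): %d dimensions evaluated\n",
              x$method, nrow(x$trace)))
  best <- x$trace[x$trace$dim == x$best_dim, ]
  cat(sprintf("best dim %d: Sn %.4f  Sp %.4f  Acc %.4f  MCC %.4f\n",
              x$best_dim, best$sn, best$sp, best$acc, best$mcc))
  invisible(x)
}

#' Cross-validated incremental feature selection on a window dataset
#'
#' The heavyweight companion of [incremental_selection()]: for each
#' fold of a stratified k-fold split it fits positional profiles and the
#' feature ranking on the training fold once, then walks the candidate
#' dimensions, refitting only the classifier on the top-`d` features.
#' Confusion counts are pooled across folds per dimension, giving the
#' accuracy-versus-dimension trace from which the best dimension is
#' selected (ties toward the smallest).
#'
#' @param dataset a labeled [sno_dataset].
#' @param config an [sno_config()] whose `selection` names the ranking
#'   method (`"ig"` or `"mrmd"`).
#' @param dims candidate dimensions (default: a doubling grid up to the
#'   full dimension).
#' @param k folds.
#' @return An `sno_selection` (see [incremental_selection()]).
#' @export
incremental_cv <- function(dataset, config = sno_config(selection = "ig"),
                           dims = NULL, k = 10L) {
  if (config$selection == "none")
    stop("config$selection must be 'ig' or 'mrmd'")
  if (any(is.na(dataset$label))) stop("dataset must be fully labeled")
  prof_enc <- intersect(config$encoders, PROFILE_ENCODERS)
  comp_enc <- intersect(config$encoders, COMPOSITION_ENCODERS)
  Xcomp <- if (length(comp_enc))
    encode_features(dataset, encoders = comp_enc,
                    lam = config$lam, w = config$w)
  folds <- stratified_folds(dataset$label, k, seed = config$seed)
  fold_data <- lapply(seq_len(k), function(f) {
    test_idx <- which(folds == f)
    if (length(prof_enc)) {
      train <- dataset[-test_idx, , drop = FALSE]
      attr(train, "t") <- window_t(dataset)
      class(train) <- class(dataset)
      profile <- fit_positional_profiles(train,
                                         smoothing = config$smoothing)
      Xprof <- encode_features(dataset$peptide, encoders = prof_enc,
                               profile = profile)
      comp_b <- attr(Xcomp, "blocks"); prof_b <- attr(Xprof, "blocks")
      X <- do.call(cbind, lapply(config$encoders, function(e) {
        if (e %in% comp_enc) Xcomp[, comp_b[[e]], drop = FALSE]
        else Xprof[, prof_b[[e]], drop = FALSE]
      }))
    } else X <- Xcomp
    ytr <- dataset$label[-test_idx]
    rk <- if (config$selection == "ig")
      rank_features_ig(X[-test_idx, , drop = FALSE], ytr)
    else
      mrmd_rank(X[-test_idx, , drop = FALSE], ytr,
                variant = config$variant)
    list(X = X, test_idx = test_idx, order = rk$order)
  })
  D <- ncol(fold_data[[1L]]$X)
  if (is.null(dims)) {
    dims <- 2^(0:floor(log2(D)))
    dims <- sort(unique(c(dims, D)))
  }
  dims <- sort(unique(as.integer(dims)))
  if (any(dims < 1L | dims > D)) stop("dims must lie in 1..", D)
  rows <- lapply(dims, function(d) {
    tp <- fp <- tn <- fn <- 0L
    for (fd in fold_data) {
      feats <- fd$order[seq_len(d)]
      set.seed(config$seed * 1000L + d)
      out <- select_fit_predict(
        fd$X[-fd$test_idx, feats, drop = FALSE],
        dataset$label[-fd$test_idx],
        fd$X[fd$test_idx, feats, drop = FALSE],
        sno_config(encoders = config$encoders, lam = config$lam,
                   w = config$w, selection = "none",
                   classifier = config$classifier,
                   smoothing = config$smoothing, seed = config$seed))
      truth <- dataset$label[fd$test_idx]
      tp <- tp + sum(truth == 1L & out$label == 1L)
      fp <- fp + sum(truth == 0L & out$label == 1L)
      tn <- tn + sum(truth == 0L & out$label == 0L)
      fn <- fn + sum(truth == 1L & out$label == 0L)
    }
    m <- metrics_from_counts(tp, fp, tn, fn)
    data.frame(dim = d, sn = m$sn, sp = m$sp, acc = m$acc, mcc = m$mcc)
  })
  trace <- do.call(rbind, rows)
  best_dim <- trace$dim[which.max(trace$acc)]
  # final ranking on the full dataset for the selected feature list
  Xfull <- if (length(prof_enc)) {
    profile <- fit_positional_profiles(dataset,
                                       smoothing = config$smoothing)
    Xprof <- encode_features(dataset$peptide, encoders = prof_enc,
                             profile = profile)
    comp_b <- attr(Xcomp, "blocks"); prof_b <- attr(Xprof, "blocks")
    do.call(cbind, lapply(config$encoders, function(e) {
      if (e %in% comp_enc) Xcomp[, comp_b[[e]], drop = FALSE]
      else Xprof[, prof_b[[e]], drop = FALSE]
    }))
  } else Xcomp
  rk_full <- if (config$selection == "ig")
    rank_features_ig(Xfull, dataset$label)
  else mrmd_rank(Xfull, dataset$label, variant = config$variant)
  structure(list(trace = trace, best_dim = best_dim,
                 features = rk_full$order[seq_len(best_dim)],
                 method = rk_full$method),
            class = "sno_selection")
}

#' Write a selection trace or ranking as TSV
#'
#' @param x an `sno_selection` or `sno_ranking`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(x, path) {
  if (inherits(x, "sno_selection")) {
    utils::write.table(x$trace, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (inherits(x, "sno_ranking")) {
    utils::write.table(
      data.frame(feature = x$order, score = x$scores,
                 rank = seq_along(x$order)),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else stop("unsupported object")
  invisible(path)
}
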