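# Pluggable binary classifiers. A classifier is a list with
#   fit(x, y)        -> fitted state (y is a 0/1 factor-compatible vector)
#   predict(state, x)-> list(label = 0/1 integer, score = numeric)
# Features are standardized per training set before fitting.

#' Classifier specifications for the prediction pipeline
#'
#' Returns a classifier spec usable by [train_predict()], [sno_fit()]
#' and [cross_validate()]. Built-ins:
#' \describe{
#'   \item{`"svm"`}{support-vector machine with RBF kernel
#'     (\pkg{e1071}); the default. `tune = TRUE` runs a small internal
#'     grid search over `C` in \{1, 10, 100\} and `gamma` in
#'     \{1/d, 0.01, 0.001\} by 5-fold cross-validation accuracy.}
#'   \item{`"logistic"`}{ridge-free logistic regression (`stats::glm`),
#'     thresholded at probability 0.5.}
#' }
#' Any user list with `fit` and `predict` of the documented signature is
#' accepted wherever a spec is.
#'
#' @param name `"svm"` or `"logistic"`.
#' @param tune logical; grid-search SVM hyperparameters (slower).
#' @param cost,gamma fixed SVM hyperparameters used when `tune = FALSE`;
#'   `gamma = NULL` means the kernel default `1/d`.
#' @return A list with elements `name`, `fit`, `predict`.
#' @export
sno_classifier <- function(name = c("svm", "logistic"), tune = FALSE,
                           cost = 1, gamma = NULL) {
  name <- match.arg(name)
  if (name == "svm") {
    list(
      name = "svm",
      fit = function(x, y) {
        yf <- factor(y, levels = c(0L, 1L))
        g <- if (is.null(gamma)) 1 / ncol(x) else gamma
        if (tune) {
          grid <- expand.grid(cost = c(1, 10, 100),
                              gamma = unique(c(1 / ncol(x), 0.01, 0.001)))
          accs <- apply(grid, 1L, function(p) {
            m <- e1071::svm(x, yf, kernel = "radial", cost = p[["cost"]],
                            gamma = p[["gamma"]], scale = FALSE, cross = 5)
            m$tot.accuracy
          })
          best <- grid[which.max(accs), ]
          cost <- best$cost; g <- best$gamma
        }
        e1071::svm(x, yf, kernel = "radial", cost = cost, gamma = g,
                   scale = FALSE, probability = FALSE)
      },
      predict = function(state, x) {
        pred <- stats::predict(state, x, decision.values = TRUE)
        dv <- attr(pred, "decision.values")
        score <- as.numeric(dv)
        # orient the decision value so larger = more likely class 1
        if (!is.null(colnames(dv)) && startsWith(colnames(dv)[1L], "0/"))
          score <- -score
        list(label = as.integer(as.character(pred)), score = score)
      })
  } else {
    list(
      name = "logistic",
      fit = function(x, y) {
        df <- as.data.frame(x)
        names(df) <- paste0("V", seq_len(ncol(x)))
        df$.y <- y
        suppressWarnings(
          stats::glm(.y ~ ., data = df, family = stats::binomial()))
      },
      predict = function(state, x) {
        df <- as.data.frame(x)
        names(df) <- paste0("V", seq_len(ncol(x)))
        p <- suppressWarnings(
          stats::predict(state, newdata = df, type = "response"))
        list(label = as.integer(p > 0.5), score = as.numeric(p))
      })
  }
}

# Per-training-set feature standardization; constant columns are left
# centered only (scale 1).
fit_scaler <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2L, stats::sd)
  sd[sd == 0 | is.na(sd)] <- 1
  list(mu = mu, sd = sd)
}

apply_scaler <- function(scaler, x) {
  sweep(sweep(x, 2L, scaler$mu, "-"), 2L, scaler$sd, "/")
}
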