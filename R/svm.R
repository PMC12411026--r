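#' Train a linear support vector machine
#'
#' L2-regularized hinge-loss SVM solved by deterministic dual coordinate
#' descent. Features may be standardized (zero mean, unit variance computed
#' on the training data); the bias term is an augmented constant feature.
#' MM is the positive class (+1), BN the negative class (-1), fixing the
#' sign convention of the weight vector.
#'
#' @param x numeric matrix (rows = instances).
#' @param y class labels, factor or character with values `"BN"`/`"MM"`.
#' @param C regularization parameter (default 1).
#' @param standardize standardize columns with training statistics
#'   (default `TRUE`); zero-variance columns are centered only.
#' @param max_epochs,tol solver controls.
#' @return an object of class `linear_svm` with elements `weights` (per
#'   feature, standardized space), `bias`, `center`, `scale`, `kernel`.
#' @export
svm_linear <- function(x, y, C = 1, standardize = TRUE,
                       max_epochs = 5000L, tol = 1e-8) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  yy <- ifelse(as.character(y) == "MM", 1, -1)
  if (length(unique(yy)) < 2L) stop_config("both classes must be present")
  if (C <= 0) stop_config("C must be > 0")
  if (standardize) {
    center <- colMeans(x)
    scl <- apply(x, 2, sd)
    scl[!is.finite(scl) | scl == 0] <- 1
  } else {
    center <- rep(0, ncol(x)); scl <- rep(1, ncol(x))
  }
  xs <- sweep(sweep(x, 2, center), 2, scl, "/")
  fit <- svm_dcd_fit(cbind(xs, 1), yy, C, as.integer(max_epochs), tol)
  structure(list(
    weights = stats::setNames(fit$w[seq_len(ncol(x))], colnames(x)),
    bias = fit$w[ncol(x) + 1L], center = center, scale = scl,
    C = C, kernel = "linear", converged = fit$converged,
    epochs = fit$epochs, levels = c("BN", "MM")
  ), class = "linear_svm")
}

#' Decision scores of a linear SVM
#'
#' @param model a [svm_linear()] fit.
#' @param x numeric matrix of instances.
#' @return signed decision values; positive means MM.
#' @export
svm_decision <- function(model, x) {
  stopifnot(inherits(model, "linear_svm"))
  x <- as.matrix(x)
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  drop(xs %*% model$weights) + model$bias
}

#' Predicted class labels of a linear SVM
#'
#' @inheritParams svm_decision
#' @return character vector of `"BN"`/`"MM"`.
#' @export
svm_predict <- function(model, x) {
  ifelse(svm_decision(model, x) > 0, "MM", "BN")
}

#' @export
print.linear_svm <- function(x, ...) {
  cat(sprintf("<linear_svm> C = %g, %d features, %s after %d epochs\n",
              x$C, length(x$weights),
              if (x$converged) "converged" else "NOT converged", x$epochs))
  invisible(x)
}
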