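#' Linear one-vs-rest SVM
#'
#' Fits one maximum-margin linear classifier per class against the rest and
#' predicts by the largest (oriented) decision value, with `C = 1` and raw
#' (unnormalized) features by default — histogram normalization is a scalar
#' rescale absorbed by the SVM.
#'
#' The LBP patch-histogram features are sparse and very high-dimensional
#' (331,776 dimensions for a nominal frame), so the problem is solved through
#' its linear Gram matrix: the kernel depends on the features only through
#' inner products, and an eigendecomposition of the centered training Gram
#' yields an exact, equivalent representation in at most `n` dimensions
#' (centering only shifts the bias term of an SVM, so the decision boundary
#' is unchanged). The reduced dense problem is solved by libsvm (e1071),
#' which is robust to the large raw-count kernel scale. Deterministic given
#' the inputs.
#'
#' `train_lbp_svm()` is the same fit, named for its role behind the LBP
#' texture pipeline.
#'
#' @param x Feature matrix (dense or `dgCMatrix`), one row per frame.
#' @param y Class labels; at least two distinct classes required.
#' @param C Regularization constant (default 1).
#'
#' @return A `cem_svm` model handle (it retains the training features, which
#'   prediction needs to evaluate the kernel).
#' @export
train_linear_svm <- function(x, y, C = 1) {
  y <- as.character(y)
  stopifnot(nrow(x) == length(y))
  classes <- unique(y)
  classes <- c(intersect(CEM_CLASS_ORDER, classes),
               sort(setdiff(classes, CEM_CLASS_ORDER)))
  if (length(classes) < 2L)
    stop("training labels contain a single class; at least two are required")
  n <- nrow(x)
  K <- as.matrix(Matrix::tcrossprod(x))
  mu <- Matrix::colMeans(x)
  xm <- as.numeric(x %*% mu)          # <x_i, mu>
  mm <- sum(mu^2)
  Kc <- K - outer(xm, rep(1, n)) - outer(rep(1, n), xm) + mm
  eg <- eigen(Kc, symmetric = TRUE)
  keep <- eg$values > max(eg$values[1], .Machine$double.eps) * 1e-10
  if (!any(keep)) keep[1] <- TRUE     # all rows identical: degenerate rank 1
  lam <- eg$values[keep]
  V <- eg$vectors[, keep, drop = FALSE]
  Z <- V %*% diag(sqrt(lam), nrow = length(lam))
  proj <- V %*% diag(1 / sqrt(lam), nrow = length(lam))  # K_c -> Z space
  fits <- lapply(classes, function(cls) {
    yb <- factor(ifelse(y == cls, "pos", "neg"), levels = c("pos", "neg"))
    fit <- e1071::svm(Z, yb, kernel = "linear", cost = C, scale = FALSE)
    d <- attr(predict(fit, Z, decision.values = TRUE), "decision.values")[, 1]
    # Orient the decision value so larger means "this class".
    flip <- mean(d[yb == "pos"]) < mean(d[yb == "neg"])
    list(fit = fit, flip = flip)
  })
  structure(list(classes = classes, fits = fits, C = C,
                 x = x, mu = mu, xm = xm, mm = mm, proj = proj),
            class = "cem_svm")
}

#' @rdname train_linear_svm
#' @export
train_lbp_svm <- function(x, y, C = 1) train_linear_svm(x, y, C = C)

#' Predict from a linear one-vs-rest SVM
#'
#' @param object A `cem_svm` from [train_linear_svm()].
#' @param newdata Feature matrix with the same number of columns as the
#'   training features.
#' @param type `"class"` (default) or `"decision"` for the per-class
#'   oriented decision values.
#' @param ... Unused.
#' @return Character vector of predicted classes, or an `N x K` decision
#'   matrix.
#' @export
predict.cem_svm <- function(object, newdata, type = c("class", "decision"), ...) {
  type <- match.arg(type)
  n <- nrow(object$x)
  Kt <- as.matrix(Matrix::tcrossprod(newdata, object$x))
  ntm <- as.numeric(newdata %*% object$mu)
  Ktc <- Kt - outer(ntm, rep(1, n)) - outer(rep(1, nrow(Kt)), object$xm) +
    object$mm
  Zt <- Ktc %*% object$proj
  dec <- vapply(object$fits, function(f) {
    d <- attr(predict(f$fit, Zt, decision.values = TRUE),
              "decision.values")[, 1]
    if (f$flip) -d else d
  }, numeric(nrow(Zt)))
  dec <- matrix(dec, nrow = nrow(Zt), dimnames = list(NULL, object$classes))
  if (type == "decision") return(dec)
  object$classes[max.col(dec, ties.method = "first")]
}

#' @export
print.cem_svm <- function(x, ...) {
  cat(sprintf("<cem_svm> linear one-vs-rest, classes: %s, C = %g\n",
              paste(x$classes, collapse = ", "), x$C))
  invisible(x)
}
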