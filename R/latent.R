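#' Principal component analysis by singular value decomposition
#'
#' Components are the right singular vectors of the (already column-centered)
#' matrix, ordered by singular value; the explained-variance fraction of
#' component i is `sigma_i^2 / sum(sigma^2)`. Sign convention: the
#' largest-magnitude element of each loading is positive.
#'
#' @param X Column-centered samples x bins matrix (e.g. Pareto-scaled).
#' @param k Number of components, `k <= min(nrow(X) - 1, ncol(X))`.
#' @return A `pca_model`: `loadings` (bins x k), `scores` (samples x k),
#'   `explained` (length-k fractions).
#' @export
fit_pca <- function(X, k = 2) {
  X <- as_matrix_values(X)
  if (k > min(nrow(X) - 1, ncol(X)))
    stop("k exceeds min(samples - 1, bins)")
  sv <- svd(X, nu = 0, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]; sign(v[which.max(abs(v))])
  }, numeric(1))
  loadings <- sweep(sv$v, 2, flip, `*`)
  structure(list(loadings = loadings,
                 scores = X %*% loadings,
                 explained = sv$d[seq_len(k)]^2 / sum(sv$d^2)),
            class = "pca_model")
}

as_matrix_values <- function(X) {
  if (inherits(X, "bin_matrix")) X$values else as.matrix(X)
}

# Core OPLS fit on scaled matrix X and centered +/-1 response yc.
# Follows the standard orthogonal-filtering recursion: per orthogonal
# component the PLS weight/loading pair is computed, the part of the loading
# orthogonal to the weight is extracted, and its variation removed from X;
# one predictive PLS component is then fitted on the residual.
opls_core <- function(X, yc, n_orth) {
  w_orth <- vector("list", n_orth); p_orth <- vector("list", n_orth)
  yy <- sum(yc^2)
  for (k in seq_len(n_orth)) {
    w <- crossprod(X, yc)[, 1] / yy
    w <- w / sqrt(sum(w^2))
    t <- X %*% w
    p <- crossprod(X, t)[, 1] / sum(t^2)
    wo <- p - sum(w * p) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12)
      stop("no orthogonal variation left: n_orth too large for rank of X")
    wo <- wo / nwo
    to <- X %*% wo
    po <- crossprod(X, to)[, 1] / sum(to^2)
    X <- X - to %*% t(po)
    w_orth[[k]] <- wo; p_orth[[k]] <- po
  }
  w <- crossprod(X, yc)[, 1] / yy
  w <- w / sqrt(sum(w^2))
  t <- X %*% w
  tt <- sum(t^2)
  p <- crossprod(X, t)[, 1] / tt
  b <- sum(t * yc) / tt
  list(w_pred = w, p_pred = p, b = b, w_orth = w_orth, p_orth = p_orth,
       scores = b * t[, 1])
}

# Remove stored orthogonal components from new data, return predicted scores.
opls_scores <- function(core, Xnew) {
  for (k in seq_along(core$w_orth)) {
    to <- Xnew %*% core$w_orth[[k]]
    Xnew <- Xnew - to %*% t(core$p_orth[[k]])
  }
  core$b * (Xnew %*% core$w_pred)[, 1]
}

#' Fit a two-class OPLS-DA model
#'
#' The class response is coded +1 (first level of `class_labels`) / -1 and
#' centered. `n_orth` orthogonal (class-unrelated) components are extracted
#' and removed from `X`, then a single predictive PLS component is fitted on
#' the residual. The decision threshold is the midpoint of the two class-mean
#' predicted training scores; at a tie the first-listed class is returned.
#'
#' @param X Samples x bins matrix, centered/Pareto-scaled by the caller.
#' @param y Class labels (two distinct values).
#' @param n_orth Number of orthogonal components (>= 0).
#' @param class_labels Ordered pair; first label is coded +1 ("positive").
#' @return An `opls_model`.
#' @export
fit_oplsda <- function(X, y, n_orth = 0, class_labels = NULL) {
  X <- as_matrix_values(X)
  y <- as.character(y)
  if (is.null(class_labels)) class_labels <- unique(y)
  if (length(class_labels) != 2 || !all(y %in% class_labels))
    stop("y must contain exactly two classes")
  if (length(unique(y)) < 2) stop("both classes must be present in y")
  if (n_orth < 0) stop("n_orth must be >= 0")
  if (n_orth >= qr(X)$rank)
    stop("n_orth must be below the rank of X")
  ypm <- ifelse(y == class_labels[1], 1, -1)
  yc <- ypm - mean(ypm)
  core <- opls_core(X, yc, n_orth)
  thr <- mean(c(mean(core$scores[ypm == 1]), mean(core$scores[ypm == -1])))
  structure(c(core[c("w_pred", "p_pred", "b", "w_orth", "p_orth")],
              list(n_orth = n_orth, class_labels = class_labels,
                   decision_threshold = thr,
                   train_column_means = colMeans(X),
                   bins = colnames(X))),
            class = "opls_model")
}

#' @export
print.opls_model <- function(x, ...) {
  cat("<opls_model>", x$class_labels[1], "vs", x$class_labels[2], ":",
      length(x$w_pred), "bins, 1 predictive +", x$n_orth,
      "orthogonal component(s)\n")
  invisible(x)
}

#' Predict class membership from an OPLS-DA model
#'
#' Orthogonal variation is removed from the new data with the stored
#' weights/loadings, predicted scores are `b * (X_deflated %*% w_pred)`, and
#' samples are assigned to the class on their side of the decision threshold
#' (ties to the first-listed class).
#'
#' @param object An `opls_model`.
#' @param newdata Samples x bins matrix scaled with the training statistics.
#' @param ... Unused.
#' @return List with `score` (numeric) and `class` (character).
#' @export
predict.opls_model <- function(object, newdata, ...) {
  newdata <- as_matrix_values(newdata)
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != length(object$w_pred))
    stop("bin mismatch: model has ", length(object$w_pred), " bins, data has ",
         ncol(newdata))
  if (!is.null(object$bins) && !is.null(colnames(newdata)) &&
      !identical(colnames(newdata), object$bins))
    stop("bin mismatch: column names differ from training bins")
  sc <- opls_scores(object, newdata)
  cls <- ifelse(sc >= object$decision_threshold,
                object$class_labels[1], object$class_labels[2])
  # ">=" puts threshold ties on the first-listed class
  list(score = sc, class = cls)
}

#' Variable importance in projection (predictive component)
#'
#' With a single predictive component, `VIP_j = sqrt(J) * |w_j| / ||w||`
#' where J is the bin count; consequently `sum(VIP^2) = J`.
#'
#' @param m An `opls_model`.
#' @return Nonnegative numeric vector of per-bin VIP scores.
#' @export
vip <- function(m) {
  stopifnot(inherits(m, "opls_model"))
  w <- m$w_pred
  sqrt(length(w)) * abs(w) / sqrt(sum(w^2))
}
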