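ordination_result <- function(coordinates, eigenvalues, proportion_explained,
                              method, negative_eigenvalues = numeric(0)) {
  k <- ncol(coordinates)
  colnames(coordinates) <- paste0("Axis", seq_len(k))
  # orient each axis so its largest-magnitude sample coordinate is positive
  for (a in seq_len(k)) {
    v <- coordinates[, a]
    if (length(v) && v[which.max(abs(v))] < 0) coordinates[, a] <- -v
  }
  structure(list(coordinates = coordinates,
                 eigenvalues = eigenvalues,
                 proportion_explained = proportion_explained,
                 method = method,
                 negative_eigenvalues = negative_eigenvalues),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("%s ordination: %d samples, %d axes\n", x$method,
              nrow(x$coordinates), ncol(x$coordinates)))
  k <- min(length(x$proportion_explained), ncol(x$coordinates))
  if (k > 0) {
    cat("proportion explained:",
        paste(sprintf("%.1f%%", 100 * x$proportion_explained[seq_len(k)]),
              collapse = ", "), "\n")
  }
  if (length(x$negative_eigenvalues)) {
    cat(sprintf("%d negative eigenvalues dropped (largest magnitude %.3g)\n",
                length(x$negative_eigenvalues),
                max(abs(x$negative_eigenvalues))))
  }
  invisible(x)
}

#' Plot the first two ordination axes
#'
#' @param x an `ordination`.
#' @param color optional numeric gradient used to shade points.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ordination <- function(x, color = NULL, ...) {
  co <- x$coordinates
  if (ncol(co) < 2) stop_value("need at least two axes to plot")
  col <- if (is.null(color)) "black" else {
    grDevices::hcl.colors(64, "Viridis")[cut(color, 64, labels = FALSE)]
  }
  graphics::plot(co[, 1], co[, 2], col = col, pch = 19,
                 xlab = colnames(co)[1], ylab = colnames(co)[2],
                 main = x$method, ...)
  invisible(x)
}

#' Principal-component analysis of a sample-by-feature matrix
#'
#' Columns are centered; sample coordinates are the projections onto the top
#' right-singular directions scaled by the singular values (so PCA of a
#' table coincides with PCoA of its Euclidean distances up to axis sign).
#' On a band table the first two axes trace the classic horseshoe.
#'
#' @param x numeric matrix with samples as rows, or a [feature_table()]
#'   (transposed internally).
#' @param n_axes number of axes to return; truncated with a warning if it
#'   exceeds the rank.
#' @return An `ordination` with eigenvalues `lambda_a = (n-1) * var(axis_a)`.
#' @export
ordinate_pca <- function(x, n_axes = 2) {
  if (inherits(x, "feature_table")) x <- t(x$values)
  x <- as.matrix(x)
  if (nrow(x) < 2) stop_value("need at least 2 samples")
  if (n_axes < 1) stop_value("n_axes must be positive")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  lambda <- pc$sdev^2 * (nrow(x) - 1)
  rank <- sum(lambda > max(lambda) * 1e-12)
  if (n_axes > rank) {
    warning("n_axes exceeds rank ", rank, "; truncated")
    n_axes <- rank
  }
  tot <- sum(lambda)
  ordination_result(pc$x[, seq_len(n_axes), drop = FALSE],
                    eigenvalues = lambda,
                    proportion_explained = if (tot > 0) lambda / tot else lambda,
                    method = "PCA")
}

#' Principal-coordinate analysis of a distance matrix
#'
#' Classical metric scaling: the squared distances are double-centered
#' (Gower) and eigendecomposed; coordinates are eigenvectors scaled by the
#' square roots of the positive eigenvalues. Negative eigenvalues -- the
#' signature of a non-Euclidean dissimilarity -- are reported and their axes
#' dropped; no Cailliez or Lingoes correction is applied, since such
#' corrections alter the very distances under study.
#'
#' @param dm a [distance_matrix()].
#' @param n_axes number of axes to return.
#' @return An `ordination`; `proportion_explained` is relative to the sum of
#'   positive eigenvalues.
#' @export
ordinate_pcoa <- function(dm, n_axes = 2) {
  stopifnot(inherits(dm, "distance_matrix"))
  if (n_axes < 1) stop_value("n_axes must be positive")
  n <- ncol(dm)
  D2 <- unclass(dm)^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% D2 %*% J
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  lambda <- eig$values
  tol <- max(abs(lambda)) * 1e-9
  pos <- which(lambda > tol)
  neg <- lambda[lambda < -tol]
  if (length(pos) == 0) {
    warning("no positive eigenvalues; returning a single degenerate axis")
    co <- matrix(0, n, 1, dimnames = list(dm_ids(dm), NULL))
    return(ordination_result(co, eigenvalues = lambda,
                             proportion_explained = rep(0, length(lambda)),
                             method = "PCoA", negative_eigenvalues = neg))
  }
  k <- min(n_axes, length(pos))
  if (n_axes > length(pos)) {
    warning("n_axes exceeds the number of positive eigenvalues (",
            length(pos), "); truncated")
  }
  co <- eig$vectors[, pos[seq_len(k)], drop = FALSE] %*%
    diag(sqrt(lambda[pos[seq_len(k)]]), k)
  rownames(co) <- dm_ids(dm)
  ordination_result(co, eigenvalues = lambda[pos],
                    proportion_explained = lambda[pos] / sum(lambda[pos]),
                    method = "PCoA", negative_eigenvalues = neg)
}

#' Correspondence analysis of a feature table
#'
#' SVD of the standardized residuals
#' `S = D_f^{-1/2} (P - f s^T) D_s^{-1/2}` of the table normalized to grand
#' total 1 (feature masses `f`, sample masses `s`). Samples are returned in
#' principal coordinates, so in full dimensionality the inter-sample
#' Euclidean distances equal the chi-squared distances of [chisq_dm()] --
#' which is why CA of a gradient-banded table shows the same arch as PCoA of
#' a saturating metric. All-zero rows/columns are dropped with a warning.
#'
#' @param table a [feature_table()] with positive grand total.
#' @param n_axes number of axes to return.
#' @return An `ordination`; eigenvalues are the principal inertias and
#'   `proportion_explained` their shares of the total inertia.
#' @export
ordinate_ca <- function(table, n_axes = 2) {
  stopifnot(inherits(table, "feature_table"))
  if (n_axes < 1) stop_value("n_axes must be positive")
  x <- table$values
  drop_f <- rowSums(x) == 0
  drop_s <- colSums(x) == 0
  if (any(drop_f) || any(drop_s)) {
    warning(sum(drop_f), " all-zero feature(s) and ", sum(drop_s),
            " all-zero sample(s) dropped")
    x <- x[!drop_f, !drop_s, drop = FALSE]
  }
  if (sum(x) <= 0) stop_value("grand total must be positive")
  P <- x / sum(x)
  f <- rowSums(P)
  s <- colSums(P)
  S <- sweep(sweep(P - outer(f, s), 1, sqrt(f), "/"), 2, sqrt(s), "/")
  sv <- svd(S)
  lambda <- sv$d^2
  tol <- if (max(lambda) > 0) max(lambda) * 1e-12 else 0
  rank <- sum(lambda > tol)
  k <- min(n_axes, max(rank, 1))
  if (n_axes > rank && rank > 0) {
    warning("n_axes exceeds rank ", rank, "; truncated")
  }
  co <- sweep(sv$v[, seq_len(k), drop = FALSE], 1, sqrt(s), "/") %*%
    diag(sv$d[seq_len(k)], k)
  rownames(co) <- colnames(x)
  tot <- sum(lambda)
  ordination_result(co, eigenvalues = lambda,
                    proportion_explained = if (tot > 0) lambda / tot else lambda,
                    method = "CA")
}

#' Detect arch curvature in the first two ordination axes
#'
#' Fits `axis2 = a * axis1^2 + b * axis1 + c` by least squares and declares
#' an arch when the quadratic term dominates:
#' `|a| * range(axis1)^2 / range(axis2) > threshold`. This is a pragmatic
#' diagnostic for the characteristic parabola-like bending of a gradient,
#' not a formal test; the default threshold 0.5 flags configurations where
#' the fitted curvature spans at least half of the axis-2 range.
#'
#' @param ordination an `ordination` with at least two axes.
#' @param threshold curvature ratio above which an arch is declared.
#' @return A list: `arch` (logical), `curvature` (the ratio), `a`
#'   (quadratic coefficient).
#' @export
detect_arch <- function(ordination, threshold = 0.5) {
  co <- ordination$coordinates
  if (ncol(co) < 2) stop_value("need two axes for arch detection")
  a1 <- co[, 1]
  a2 <- co[, 2]
  r2 <- diff(range(a2))
  if (r2 <= .Machine$double.eps) {
    return(list(arch = FALSE, curvature = 0, a = 0))
  }
  fit <- stats::lm(a2 ~ a1 + I(a1^2))
  a <- unname(stats::coef(fit)[3])
  if (is.na(a)) a <- 0
  curv <- abs(a) * diff(range(a1))^2 / r2
  list(arch = curv > threshold, curvature = curv, a = a)
}

#' Horseshoe / single-axis-gradient test of an ordination
#'
#' Operationalizes "does this embedding bend the gradient?": computes the
#' Spearman rank correlation between axis 1 and the sample gradient, the
#' arch diagnostic of [detect_arch()], and the endpoint sign test (both
#' gradient extremes on the same side of the axis-2 median while the
#' gradient midpoint sits on the other side -- the hallmark of the ends of
#' a horseshoe curling toward each other). An ordination "passes the
#' single-axis gradient test" when axis 1 alone carries the gradient
#' (`|rho| >= 0.99`) and no arch is detected.
#'
#' @param ordination an `ordination`.
#' @param gradient numeric gradient, aligned with the ordination's samples
#'   (names matched if present).
#' @return A list: `axis1_spearman`, `arch` (from [detect_arch()]),
#'   `endpoint_sign_horseshoe` (logical), `single_axis_gradient` (logical).
#' @export
horseshoe_test <- function(ordination, gradient) {
  co <- ordination$coordinates
  if (!is.null(names(gradient)) && !is.null(rownames(co))) {
    gradient <- gradient[rownames(co)]
  }
  rho <- stats::cor(co[, 1], gradient, method = "spearman")
  arch <- if (ncol(co) >= 2) detect_arch(ordination) else
    list(arch = FALSE, curvature = 0, a = 0)
  sign_test <- FALSE
  if (ncol(co) >= 2) {
    ord <- order(gradient)
    a2 <- co[, 2]
    med <- stats::median(a2)
    lo <- a2[ord[1]] - med
    hi <- a2[ord[length(ord)]] - med
    mid <- a2[ord[ceiling(length(ord) / 2)]] - med
    sign_test <- (sign(lo) == sign(hi)) && (sign(mid) != sign(lo))
  }
  list(axis1_spearman = unname(rho),
       arch = arch,
       endpoint_sign_horseshoe = sign_test,
       single_axis_gradient = abs(rho) >= 0.99 && !arch$arch)
}
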