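#' Median-expression filter before PCA
#'
#' Keeps genes whose within-cohort median FPKM reaches `min_median` in at
#' least one cohort (boundary inclusive).
#'
#' @param matrix Gene-by-sample numeric matrix.
#' @param design Design data.frame covering all samples.
#' @param min_median FPKM threshold (default 1).
#' @return The filtered matrix.
#' @export
pca_filter <- function(matrix, design, min_median = 1.0) {
  d <- match_design(matrix, design)
  cohorts <- levels(droplevels(d$cohort))
  keep <- rep(FALSE, nrow(matrix))
  for (co in cohorts) {
    cols <- d$cohort == co
    med <- apply(matrix[, cols, drop = FALSE], 1L, stats::median)
    keep <- keep | med >= min_median
  }
  if (!any(keep))
    stop("no gene passes the median filter; lower min_median")
  matrix[keep, , drop = FALSE]
}

#' PCA of samples on log2(FPKM + 1)
#'
#' Gene-centred, not variance-scaled principal components of the samples.
#' Components are ordered by decreasing explained variance and carry a
#' deterministic sign convention: within each component the largest-magnitude
#' gene loading is positive.
#'
#' @param matrix Gene-by-sample numeric matrix on the log2(FPKM + 1) scale
#'   (see [log_transform()]).
#' @param n_components Number of components to return (default 2); must not
#'   exceed min(genes, samples - 1).
#' @return A list: `scores` (sample x component), `loadings`
#'   (gene x component), `variance_fraction` (per returned component, of the
#'   total variance across all components), `total_components`.
#' @export
run_pca <- function(matrix, n_components = 2L) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) stop("matrix must be numeric")
  max_comp <- min(nrow(matrix), ncol(matrix) - 1L)
  if (n_components < 1L || n_components > max_comp)
    stop("n_components must be between 1 and min(genes, samples - 1) = ", max_comp)
  fit <- stats::prcomp(t(matrix), center = TRUE, scale. = FALSE)
  var_all <- fit$sdev^2
  keep <- seq_len(n_components)
  scores <- fit$x[, keep, drop = FALSE]
  loadings <- fit$rotation[, keep, drop = FALSE]
  # sign convention: largest-magnitude loading positive per component
  for (j in keep) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores, loadings = loadings,
       variance_fraction = var_all[keep] / sum(var_all),
       total_components = length(var_all))
}

#' Cohort confidence ellipse on 2-D PCA scores
#'
#' Covariance-coverage ellipse: centred on the member mean, with semi-axis
#' lengths sqrt(chi2_2(coverage) * eigenvalues) of the members' 2x2 score
#' covariance and rotation from its eigenvectors. A zero-variance direction
#' is flagged degenerate, not an error.
#'
#' @param scores Sample x 2 numeric score matrix with sample rownames.
#' @param members Sample ids (or row indices) of the cohort; at least 3.
#' @param coverage Nominal coverage probability (default 0.95).
#' @return A list: `center` (length 2), `axes` (semi-axis lengths, decreasing),
#'   `angle` (radians, rotation of the major axis), `covariance` (2x2),
#'   `coverage`, `degenerate` (logical).
#' @export
confidence_ellipse <- function(scores, members, coverage = 0.95) {
  if (ncol(scores) < 2L) stop("scores must have at least 2 columns")
  pts <- if (is.character(members)) scores[members, 1:2, drop = FALSE]
         else scores[members, 1:2, drop = FALSE]
  if (nrow(pts) < 3L) stop("need at least 3 member samples")
  if (coverage <= 0 || coverage >= 1) stop("coverage must be in (0, 1)")
  center <- colMeans(pts)
  covm <- stats::cov(pts)
  eig <- eigen(covm, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  q <- stats::qchisq(coverage, df = 2)
  axes <- sqrt(q * lambda)
  angle <- atan2(eig$vectors[2, 1], eig$vectors[1, 1])
  list(center = center, axes = axes, angle = angle, covariance = covm,
       coverage = coverage, degenerate = any(lambda <= .Machine$double.eps * max(lambda, 1)))
}

#' Test whether points fall inside a confidence ellipse
#'
#' Mahalanobis membership test against the ellipse's covariance and
#' chi-square radius; used for coverage checks.
#'
#' @param ellipse Ellipse list from [confidence_ellipse()].
#' @param points n x 2 numeric matrix.
#' @return Logical vector, TRUE when the point lies inside (or on) the
#'   ellipse.
#' @export
ellipse_contains <- function(ellipse, points) {
  if (ellipse$degenerate)
    stop("degenerate ellipse: containment undefined in a zero-variance direction")
  d2 <- stats::mahalanobis(points, ellipse$center, ellipse$covariance)
  d2 <= stats::qchisq(ellipse$coverage, df = 2)
}

#' Scatter plot of PCA scores with cohort ellipses
#'
#' @param pca Result of [run_pca()].
#' @param design Design data.frame covering the score rows.
#' @param coverage Ellipse coverage (default 0.95).
#' @param ... Passed to [graphics::plot()].
#' @export
plot_pca <- function(pca, design, coverage = 0.95, ...) {
  scores <- pca$scores
  d <- design[match(rownames(scores), design$sample_id), , drop = FALSE]
  cohorts <- levels(droplevels(d$cohort))
  cols <- stats::setNames(seq_along(cohorts) + 1L, cohorts)
  graphics::plot(scores[, 1], scores[, 2],
                 col = cols[as.character(d$cohort)], pch = 19,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * pca$variance_fraction[1]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * pca$variance_fraction[2]),
                 ...)
  theta <- seq(0, 2 * pi, length.out = 181L)
  for (co in cohorts) {
    members <- d$sample_id[d$cohort == co]
    if (length(members) < 3L) next
    ell <- confidence_ellipse(scores, members, coverage)
    if (ell$degenerate) next
    rot <- matrix(c(cos(ell$angle), sin(ell$angle),
                    -sin(ell$angle), cos(ell$angle)), 2L)
    ring <- t(rot %*% rbind(ell$axes[1] * cos(theta), ell$axes[2] * sin(theta)))
    graphics::lines(ring[, 1] + ell$center[1], ring[, 2] + ell$center[2],
                    col = cols[co])
  }
  graphics::legend("topright", legend = cohorts, col = cols[cohorts], pch = 19)
  invisible(pca)
}
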