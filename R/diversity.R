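#' Bray-Curtis distance matrix between samples
#'
#' Computes `d(u, v) = sum |u_f - v_f| / sum (u_f + v_f)` between all sample
#' pairs of an abundance table (via [vegan::vegdist()]). By convention the
#' distance between two all-zero samples is 0. On normalized tables the
#' distance is bounded in `[0, 1]`.
#'
#' @param x an [abundance_table()] (or non-negative matrix, features x
#'   samples) with at least two samples.
#' @return symmetric numeric matrix with zero diagonal, labeled by sample id.
#' @examples
#' m <- cbind(s1 = c(2, 2), s2 = c(1, 3))
#' rownames(m) <- c("a", "b")
#' bray_curtis(abundance_table(m))["s1", "s2"]  # 0.25
#' @export
bray_curtis <- function(x) {
  x <- as_abundance_table(x)
  if (ncol(x$values) < 2L) stop_validation("need at least 2 samples for a distance matrix")
  d <- suppressWarnings(vegan::vegdist(t(x$values), method = "bray"))
  m <- as.matrix(d)
  m[is.nan(m)] <- 0  # pairs of all-zero samples
  diag(m) <- 0
  m
}

#' Principal Coordinate Analysis (classical MDS)
#'
#' Eigendecomposition of the double-centered squared-distance matrix
#' `-1/2 * J D^2 J` (via [stats::cmdscale()]). Coordinates are the
#' eigenvectors scaled by the square root of their (positive) eigenvalues;
#' axes are ordered by decreasing eigenvalue. Negative eigenvalues — possible
#' for non-Euclidean distances such as Bray-Curtis — are reported in
#' `eigenvalues` but excluded from the coordinates and from the
#' variance-explained denominator; the optional Cailliez correction adds a
#' constant to off-diagonal distances to remove them. For determinism each
#' axis is reflected so that its largest-magnitude loading is positive.
#'
#' @param d distance matrix (square symmetric matrix or `dist`).
#' @param n_axes number of coordinate axes requested (at most
#'   `n_samples - 1`; fewer are returned when trailing eigenvalues are not
#'   positive).
#' @param correction `"none"` (default) or `"cailliez"`.
#' @return object of class `pcoa_result`: `coordinates` (samples x axes),
#'   `eigenvalues` (all, decreasing), `proportion_explained` (per retained
#'   axis, relative to the sum of positive eigenvalues).
#' @export
pcoa <- function(d, n_axes = 2L, correction = c("none", "cailliez")) {
  correction <- match.arg(correction)
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop_validation("'d' must be a square distance matrix")
  if (any(!is.finite(d)) || any(d < 0)) stop_validation("distances must be finite and non-negative")
  if (max(abs(d - t(d))) > 1e-8) stop_validation("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop_validation("distance matrix must have a zero diagonal")
  n <- nrow(d)
  if (!is_count(n_axes) || n_axes > n - 1L) {
    stop_validation("'n_axes' must be a positive integer <= n_samples - 1")
  }
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = n_axes, eig = TRUE,
                                          add = correction == "cailliez"))
  pts <- fit$points
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 1L)
  # drop axes tied to non-positive eigenvalues (cmdscale can return NA columns)
  keep <- which(fit$eig[seq_len(ncol(pts))] > 0 & !apply(pts, 2, anyNA))
  pts <- pts[, keep, drop = FALSE]
  for (j in seq_len(ncol(pts))) {
    if (pts[which.max(abs(pts[, j])), j] < 0) pts[, j] <- -pts[, j]
  }
  colnames(pts) <- paste0("Axis.", seq_len(ncol(pts)))
  rownames(pts) <- rownames(d) %||% paste0("sample", seq_len(n))
  eig <- sort(fit$eig, decreasing = TRUE)
  pos_sum <- sum(eig[eig > 0])
  prop <- if (pos_sum > 0) eig[seq_len(ncol(pts))] / pos_sum else rep(NA_real_, ncol(pts))
  structure(list(coordinates = pts, eigenvalues = eig,
                 proportion_explained = prop, correction = correction),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("pcoa_result: %d sample(s), %d axis/axes (%s correction)\n",
              nrow(x$coordinates), ncol(x$coordinates), x$correction))
  cat("proportion explained:", paste(sprintf("%.3f", x$proportion_explained), collapse = ", "), "\n")
  invisible(x)
}
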