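#' Precision, recall and F1 against ground truth
#'
#' Binary clustered-vs-noise comparison per localization: cluster identity is
#' ignored, matching the standard scoring of SMLM cluster detection. A
#' localization is "clustered" when its label is `>= 0` and noise when it is
#' `-1`. Then `TP` = truth-clustered and predicted-clustered, `FP` =
#' truth-noise but predicted-clustered, `FN` = truth-clustered but predicted
#' noise, and
#' \deqn{P = TP/(TP+FP), \quad R = TP/(TP+FN), \quad F1 = 2PR/(P+R).}
#'
#' Degenerate conventions: if nothing is predicted clustered (`TP+FP = 0`),
#' `P = 0` and `F1 = 0`; if the truth has no clustered points (`TP+FN = 0`),
#' `R = 1` and the report is flagged.
#'
#' @param labels Predicted per-localization labels (`-1` = noise).
#' @param truth Ground-truth labels of the same length.
#' @return A list of class `confusion_report` with `TP`, `FP`, `FN`, `TN`,
#'   `precision`, `recall`, `f1` and `flag`.
#' @export
confusion_report <- function(labels, truth) {
  if (length(labels) != length(truth))
    stop("labels (", length(labels), ") and truth (", length(truth),
         ") differ in length")
  pc <- labels >= 0L
  tc <- truth >= 0L
  TP <- sum(pc & tc); FP <- sum(pc & !tc)
  FN <- sum(!pc & tc); TN <- sum(!pc & !tc)
  flag <- NULL
  P <- if (TP + FP > 0L) TP / (TP + FP) else 0
  R <- if (TP + FN > 0L) TP / (TP + FN) else { flag <- "no-true-positives-possible"; 1 }
  F1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  structure(list(TP = TP, FP = FP, FN = FN, TN = TN,
                 precision = P, recall = R, f1 = F1, flag = flag),
            class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, ...) {
  cat(sprintf("confusion: TP %d  FP %d  FN %d  TN %d\n", x$TP, x$FP, x$FN, x$TN))
  cat(sprintf("P = %.4f  R = %.4f  F1 = %.4f%s\n", x$precision, x$recall,
              x$f1, if (!is.null(x$flag)) paste0("  [", x$flag, "]") else ""))
  invisible(x)
}

#' Cluster-level silhouette score
#'
#' Measures cluster separation relative to compactness:
#' \deqn{S_C = (\bar d_{NN} - \bar d_C) / \bar d_{NN}}
#' where \eqn{\bar d_C} is the mean intra-cluster distance and
#' \eqn{\bar d_{NN}} the mean nearest-neighbour cluster distance. \eqn{S_C}
#' ranges up to 1, with larger values indicating better-separated, tighter
#' clusters. Noise points are excluded.
#'
#' Two estimator choices exist for a one-line formula; both are reported in
#' the result's metadata:
#' \itemize{
#'   \item `intra = "pairwise"` (default): \eqn{\bar d_C} is the mean over
#'     clusters of the average pairwise distance among member localizations.
#'     Clusters above `subsample` members are thinned deterministically
#'     (evenly spaced by row order) before the pairwise average.
#'   \item `intra = "centroid"`: mean member-to-centroid distance.
#' }
#' \eqn{\bar d_{NN}} is the mean over clusters of the distance from each
#' cluster centroid to the nearest other cluster centroid.
#'
#' @param fit A [focal3d()] fit, or an integer label vector (`-1` = noise).
#' @param table Localization table (required when `fit` is a label vector;
#'   otherwise taken from the fit).
#' @param intra Intra-cluster distance estimator, `"pairwise"` or
#'   `"centroid"`.
#' @param subsample Maximum members per cluster entering the pairwise
#'   average; default 500.
#' @return A list of class `silhouette_report` with `score`, `d_nn_mean`,
#'   `d_c_mean`, per-cluster components and the estimator definition used.
#' @export
silhouette_score <- function(fit, table = NULL, intra = c("pairwise", "centroid"),
                             subsample = 500L) {
  intra <- match.arg(intra)
  if (inherits(fit, "focal3d")) {
    labels <- fit$labels
    xyz <- fit$points
  } else {
    labels <- as.integer(fit)
    if (is.null(table)) stop("`table` is required when `fit` is a label vector")
    xyz <- as_localizations(table)
  }
  ids <- sort(unique(labels[labels >= 0L]))
  if (length(ids) < 2L)
    stop("silhouette score is undefined for fewer than 2 clusters")
  K <- length(ids)
  cent <- matrix(NA_real_, K, 3L)
  d_c <- numeric(K)
  for (k in seq_len(K)) {
    m <- which(labels == ids[k])
    pts <- xyz[m, , drop = FALSE]
    cent[k, ] <- colMeans(pts)
    if (intra == "centroid") {
      d_c[k] <- mean(sqrt(rowSums(sweep(pts, 2L, cent[k, ])^2)))
    } else {
      if (nrow(pts) > subsample)
        pts <- pts[round(seq(1L, nrow(pts), length.out = subsample)), ,
                   drop = FALSE]
      d_c[k] <- if (nrow(pts) >= 2L) mean(dist(pts)) else 0
    }
  }
  cd <- as.matrix(dist(cent))
  diag(cd) <- Inf
  d_nn <- apply(cd, 1L, min)
  dnn_bar <- mean(d_nn)
  dc_bar <- mean(d_c)
  structure(list(score = (dnn_bar - dc_bar) / dnn_bar,
                 d_nn_mean = dnn_bar, d_c_mean = dc_bar,
                 per_cluster = data.frame(id = ids, d_c = d_c, d_nn = d_nn),
                 intra = intra, subsample = as.integer(subsample)),
            class = "silhouette_report")
}

#' @export
print.silhouette_report <- function(x, ...) {
  cat(sprintf("silhouette S_C = %.3f  (d_NN = %.1f nm, d_C = %.1f nm; intra = %s)\n",
              x$score, x$d_nn_mean, x$d_c_mean, x$intra))
  invisible(x)
}

#' Convex-hull effective radius of a point set
#'
#' Volume of the 3D convex hull of the points and the radius of the sphere of
#' equal volume, \eqn{r_{eff} = (3 V_{hull}/(4\pi))^{1/3}}. Requires at least
#' 4 points in general position; degenerate (collinear/coplanar) sets yield
#' `NA` with `degenerate = TRUE`.
#'
#' @param points An n x 3 coordinate matrix or data frame (nm).
#' @return A list with `volume` (nm^3), `effective_radius` (nm), `n_points`,
#'   and `degenerate`.
#' @examples
#' corners <- as.matrix(expand.grid(c(0, 2), c(0, 2), c(0, 2)))
#' hull_radius(corners)  # volume 8, r_eff = (6/pi)^(1/3)
#' @export
hull_radius <- function(points) {
  pts <- as_localizations(points)
  v <- if (nrow(pts) >= 4L) cpp_hull_volume(pts) else NA_real_
  list(volume = v,
       effective_radius = if (is.na(v)) NA_real_ else (3 * v / (4 * pi))^(1 / 3),
       n_points = nrow(pts),
       degenerate = is.na(v))
}

#' Per-cluster effective radii of a clustering
#'
#' Convex-hull effective radius for every cluster of a fit, the diagnostic
#' used to spot spurious small clusters (low minC) and cluster merging (a
#' long right tail at overly coarse grids).
#'
#' @param fit A [focal3d()] fit.
#' @return Data frame with `id`, `n_localizations`, `volume`,
#'   `effective_radius` (NA where undefined).
#' @export
cluster_radii <- function(fit) {
  stopifnot(inherits(fit, "focal3d"))
  ids <- fit$clusters$id
  out <- data.frame(id = ids,
                    n_localizations = fit$clusters$n_localizations,
                    volume = rep(NA_real_, length(ids)),
                    effective_radius = rep(NA_real_, length(ids)))
  for (i in seq_along(ids)) {
    m <- fit$labels == ids[i]
    if (sum(m) >= 4L) {
      h <- hull_radius(fit$points[m, , drop = FALSE])
      out$volume[i] <- h$volume
      out$effective_radius[i] <- h$effective_radius
    }
  }
  out
}

#' 3D Ripley's K, L and H functions
#'
#' Cumulative pair-count statistic of a 3D point pattern:
#' \deqn{K(r) = \frac{V}{n(n-1)} \sum_{i \ne j} 1[d_{ij} \le r]}
#' with \eqn{L(r) = (3K(r)/4\pi)^{1/3}} and the centred \eqn{H(r) = L(r) - r}.
#' Under complete spatial randomness \eqn{H(r) \approx 0}; a peak in H marks
#' the dominant clustering length scale. No edge correction is applied by
#' default (adequate when the cluster scale is much smaller than the box
#' side); `toroidal = TRUE` wraps distances around the box.
#'
#' @param table Localization table (n >= 2 points).
#' @param radii Ascending vector of evaluation radii (nm).
#' @param box 2x3 analysis box; default the data's bounding box.
#' @param toroidal Use minimum-image (wrapped) distances. Default `FALSE`.
#' @param max_points Subsample cap for tractability of the O(n^2) pair count;
#'   deterministic even thinning. Default 5000.
#' @return An object of class `ripley_curve`: data frame with `r`, `K`, `L`,
#'   `H`, `dH` (finite-difference derivative), plus attributes
#'   `r_peak` (argmax of H) and `r_deriv_zero` (first zero crossing of dH/dr,
#'   linearly interpolated) — both cluster-scale estimates.
#' @export
ripley_k <- function(table, radii, box = NULL, toroidal = FALSE,
                     max_points = 5000L) {
  xyz <- as_localizations(table)
  n0 <- nrow(xyz)
  if (n0 < 2L) stop("Ripley's K requires at least 2 points")
  radii <- as.numeric(radii)
  if (is.unsorted(radii)) stop("`radii` must be ascending")
  if (is.null(box)) box <- rbind(apply(xyz, 2, min), apply(xyz, 2, max))
  box <- as.matrix(box)
  if (n0 > max_points)
    xyz <- xyz[round(seq(1L, n0, length.out = max_points)), , drop = FALSE]
  n <- nrow(xyz)
  V <- prod(box[2L, ] - box[1L, ])
  if (toroidal) {
    side <- box[2L, ] - box[1L, ]
    dd <- 0
    for (a in 1:3) {
      da <- abs(outer(xyz[, a], xyz[, a], "-"))
      da <- pmin(da, side[a] - da)
      dd <- dd + da^2
    }
    d <- sqrt(dd[lower.tri(dd)])
  } else {
    d <- as.numeric(dist(xyz))
  }
  cnt <- vapply(radii, function(r) sum(d <= r), 0)  # unordered pairs
  K <- V * 2 * cnt / (n * (n - 1))
  L <- (3 * K / (4 * pi))^(1 / 3)
  H <- L - radii
  dH <- c(NA, diff(H) / diff(radii))
  out <- data.frame(r = radii, K = K, L = L, H = H, dH = dH)
  r_peak <- radii[which.max(H)]
  r_dz <- NA_real_
  ip <- which.max(H)
  if (ip < length(radii)) {
    sgn <- dH[-1L]
    i <- which(sgn[-length(sgn)] > 0 & sgn[-1L] <= 0)
    if (length(i) > 0L) {
      i <- i[1L]
      # dH[i+1] > 0 >= dH[i+2]; interpolate between midpoints of the steps
      r1 <- (radii[i] + radii[i + 1L]) / 2
      r2 <- (radii[i + 1L] + radii[i + 2L]) / 2
      a <- dH[i + 1L]; b <- dH[i + 2L]
      r_dz <- if (a == b) r1 else r1 + a * (r2 - r1) / (a - b)
    }
  }
  structure(out, r_peak = r_peak, r_deriv_zero = r_dz, box = box,
            n_points = n, class = c("ripley_curve", "data.frame"))
}

#' @export
print.ripley_curve <- function(x, ...) {
  cat(sprintf("Ripley curve: %d radii in [%g, %g] nm over %d points\n",
              nrow(x), min(x$r), max(x$r), attr(x, "n_points")))
  cat(sprintf("  H peak at r = %g nm; dH/dr zero crossing at r = %s nm\n",
              attr(x, "r_peak"),
              format(attr(x, "r_deriv_zero"), digits = 4)))
  invisible(x)
}

#' @export
plot.ripley_curve <- function(x, ...) {
  graphics::plot(x$r, x$H, type = "l", xlab = "r (nm)", ylab = "H(r) (nm)",
                 main = "Ripley's H function", ...)
  graphics::abline(h = 0, lty = 3)
  graphics::abline(v = attr(x, "r_peak"), col = "red", lty = 2)
  invisible(x)
}
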