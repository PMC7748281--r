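#' FOCAL3D: voxel-grid density clustering of SMLM localizations
#'
#' Clusters a 3D single-molecule localization table by (i) binning the
#' localizations onto a cubic grid of spacing `delta`, (ii) building a
#' contrast-enhanced density map (3x3x3 neighbourhood sums over occupied
#' voxels), (iii) classifying voxels with enhanced density at or above `minL`
#' as core and occupied sub-threshold face-neighbours of core as border, and
#' (iv) keeping connected candidates (core components plus attached border)
#' of at least `minC` voxels. Every localization falling in a retained
#' cluster's core or border voxel receives that cluster's label; all others
#' are noise.
#'
#' The result is deterministic given the table and parameters, and invariant
#' to input row permutation up to the canonical cluster numbering (ascending
#' minimum core-voxel linear index).
#'
#' @param table Localization table: data frame with numeric `x`, `y`, `z`
#'   columns (nm), a matrix, or a [read_localizations()] result.
#' @param delta Grid spacing \eqn{\Delta} in nm.
#' @param minL Density threshold (localizations) applied to the enhanced map.
#' @param minC Minimum cluster size in connected voxels (core + border).
#' @param bounds Optional 2x3 analysis box (see [build_density_map()]).
#' @param connectivity Core-core connectivity, 6 (default) or 26.
#' @param inclusive,strict_edges Threshold and edge-of-volume handling flags,
#'   see [classify_voxels()].
#' @return An object of class `focal3d`: list with
#'   \describe{
#'     \item{labels}{integer vector, one per input row: cluster id `0..K-1`
#'       or `-1` for noise.}
#'     \item{clusters}{data frame with one row per cluster: `id`, `n_voxels`,
#'       `n_core`, `n_border`, `n_localizations`, `centroid_x/y/z` (nm).}
#'     \item{voxels}{list of per-cluster core/border linear voxel indices.}
#'     \item{params}{list of the clustering parameters used.}
#'     \item{grid}{grid geometry (origin, delta, dims).}
#'   }
#' @examples
#' set.seed(1)
#' blob <- function(cx) data.frame(x = rnorm(200, cx, 20),
#'                                 y = rnorm(200, 500, 20),
#'                                 z = rnorm(200, 500, 20))
#' fit <- focal3d(rbind(blob(300), blob(800)), delta = 40, minL = 5, minC = 2)
#' fit
#' table(fit$labels)
#' @seealso [focal_scan()] and [optimize_minL()] for objective parameter
#'   selection; [simulate_smlm()] for synthetic benchmarks.
#' @export
focal3d <- function(table, delta, minL, minC, bounds = NULL,
                    connectivity = 6, inclusive = TRUE, strict_edges = FALSE) {
  xyz <- as_localizations(table)
  grid <- build_density_map(xyz, delta, bounds)
  if (grid$n_points == 0L) {
    return(new_focal3d(integer(0), list(), grid, xyz,
                       params = list(delta = delta, minL = minL, minC = minC,
                                     connectivity = connectivity,
                                     inclusive = inclusive,
                                     strict_edges = strict_edges)))
  }
  edm <- enhance_density_map(grid)
  cls <- classify_voxels(edm, minL, inclusive = inclusive,
                         strict_edges = strict_edges)
  vc <- extract_clusters(cls, minC, connectivity = connectivity)
  new_focal3d(label_points(grid, vc), vc$clusters, grid, xyz,
              params = list(delta = delta, minL = minL, minC = minC,
                            connectivity = connectivity,
                            inclusive = inclusive,
                            strict_edges = strict_edges))
}

# map localizations to cluster labels (-1 noise, 0..K-1 clusters)
label_points <- function(grid, vc) {
  labels <- rep(-1L, grid$n_points)
  if (length(vc$clusters) == 0L) return(labels)
  all_vox <- unlist(lapply(vc$clusters, function(cl) c(cl$core, cl$border)))
  owner <- rep(seq_along(vc$clusters) - 1L,
               vapply(vc$clusters, function(cl)
                 length(cl$core) + length(cl$border), 0L))
  hit <- match(grid$point_voxel, all_vox)
  labels[!is.na(hit)] <- owner[hit[!is.na(hit)]]
  labels
}

new_focal3d <- function(labels, clusters, grid, xyz, params) {
  K <- length(clusters)
  if (K > 0L) {
    nloc <- tabulate(labels + 1L, nbins = K)
    cent <- matrix(NA_real_, K, 3L)
    for (k in seq_len(K)) {
      m <- labels == k - 1L
      if (any(m)) cent[k, ] <- colMeans(xyz[m, , drop = FALSE])
    }
    cl_df <- data.frame(
      id = seq_len(K) - 1L,
      n_voxels = vapply(clusters, function(cl)
        length(cl$core) + length(cl$border), 0L),
      n_core = vapply(clusters, function(cl) length(cl$core), 0L),
      n_border = vapply(clusters, function(cl) length(cl$border), 0L),
      n_localizations = nloc,
      centroid_x = cent[, 1L], centroid_y = cent[, 2L], centroid_z = cent[, 3L])
  } else {
    cl_df <- data.frame(id = integer(0), n_voxels = integer(0),
                        n_core = integer(0), n_border = integer(0),
                        n_localizations = integer(0),
                        centroid_x = numeric(0), centroid_y = numeric(0),
                        centroid_z = numeric(0))
  }
  structure(list(labels = labels, clusters = cl_df, voxels = clusters,
                 params = params,
                 grid = list(origin = grid$origin, delta = grid$delta,
                             dims = grid$dims),
                 points = xyz),
            class = "focal3d")
}

#' @export
print.focal3d <- function(x, ...) {
  p <- x$params
  cat("FOCAL3D clustering\n")
  cat(sprintf("  parameters: delta = %g nm, minL = %g, minC = %g\n",
              p$delta, p$minL, p$minC))
  cat(sprintf("  grid: %d x %d x %d voxels\n",
              x$grid$dims[1], x$grid$dims[2], x$grid$dims[3]))
  n <- length(x$labels)
  nn <- sum(x$labels == -1L)
  cat(sprintf("  localizations: %d (%d clustered, %d noise)\n",
              n, n - nn, nn))
  cat(sprintf("  clusters: %d\n", nrow(x$clusters)))
  invisible(x)
}

#' Summarize a FOCAL3D clustering
#'
#' Per-cluster table augmented with the convex-hull effective radius
#' \eqn{r_{eff} = (3 V_{hull} / 4\pi)^{1/3}} of each cluster's member
#' localizations (NA for clusters with fewer than 4 points or a degenerate
#' hull).
#'
#' @param object A `focal3d` fit.
#' @param ... Unused.
#' @return A `summary.focal3d` object: the cluster table with an
#'   `effective_radius` column plus overall counts.
#' @export
summary.focal3d <- function(object, ...) {
  cl <- object$clusters
  cl$effective_radius <- cluster_radii(object)$effective_radius
  structure(list(clusters = cl,
                 n_localizations = length(object$labels),
                 n_noise = sum(object$labels == -1L),
                 params = object$params),
            class = "summary.focal3d")
}

#' @export
print.summary.focal3d <- function(x, ...) {
  cat(sprintf("FOCAL3D clustering: %d clusters, %d/%d localizations clustered\n",
              nrow(x$clusters), x$n_localizations - x$n_noise,
              x$n_localizations))
  if (nrow(x$clusters) > 0L) {
    r <- x$clusters$effective_radius
    if (any(is.finite(r)))
      cat(sprintf("  effective radius (convex hull): %.1f +/- %.1f nm\n",
                  mean(r, na.rm = TRUE), sd(r, na.rm = TRUE)))
    print(utils::head(x$clusters, 10))
    if (nrow(x$clusters) > 10L)
      cat(sprintf("  ... %d more clusters\n", nrow(x$clusters) - 10L))
  }
  invisible(x)
}

#' Plot a FOCAL3D clustering (lateral projection)
#'
#' Scatter of the localizations projected on the x-y plane, noise in grey and
#' clusters coloured.
#'
#' @param x A `focal3d` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.focal3d <- function(x, ...) {
  pts <- x$points
  lab <- x$labels
  K <- nrow(x$clusters)
  cols <- rep("grey80", length(lab))
  if (K > 0L) {
    pal <- grDevices::hcl.colors(max(3L, K), "Dark 3")
    cols[lab >= 0L] <- pal[(lab[lab >= 0L] %% max(3L, K)) + 1L]
  }
  graphics::plot(pts[, 1L], pts[, 2L], col = cols, pch = 16, cex = 0.4,
                 xlab = "x (nm)", ylab = "y (nm)",
                 main = sprintf("FOCAL3D: %d clusters", K), ...)
  invisible(x)
}
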