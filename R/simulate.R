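#' Describe a population of simulated SMLM clusters
#'
#' A population is a set of spherically symmetric clusters sharing the same
#' generative statistics: cluster radii drawn from a Gaussian (truncated at
#' zero) with the given mean and sd; a Poisson-distributed number of dyes per
#' cluster placed uniformly throughout the cluster sphere; each dye blinking
#' into a geometrically distributed number of localizations (mean
#' `locs_per_dye_mean`, support starting at 1 — the discrete analogue of an
#' exponential blink law); each localization scattered about its dye with an
#' anisotropic Gaussian whose per-localization widths are drawn from
#' log-normal precision distributions with means `precision_xy` (lateral) and
#' `precision_z` (axial).
#'
#' The blink mean may alternatively be specified through the ON-time/blink
#' parameters as `tau_on / (1 - exp(-1/lambda))`; if both forms are given
#' they must agree to within 1e-9 relative.
#'
#' @param n_clusters Number of clusters in this population.
#' @param radius_mean,radius_sd Cluster radius distribution (nm).
#' @param dyes_mean Mean number of dyes per cluster (Poisson).
#' @param locs_per_dye_mean Mean localizations (blinks) per dye; default 10.
#' @param tau_on,lambda Optional blink-model parameters: mean ON time of a
#'   blink (in blink events) and characteristic number of blinks; their
#'   combination `tau_on/(1 - exp(-1/lambda))` sets the blink mean.
#' @param precision_xy,precision_z Mean lateral/axial localization precision
#'   (nm); defaults 10 and 20.
#' @param precision_cv Coefficient of variation of the log-normal precision
#'   law (0 gives fixed widths); default 0.25.
#' @param min_separation Minimum pairwise distance between cluster centroids
#'   (nm).
#' @return A list of class `smlm_population`.
#' @export
smlm_population <- function(n_clusters, radius_mean, radius_sd, dyes_mean,
                            locs_per_dye_mean = NULL, tau_on = NULL,
                            lambda = NULL, precision_xy = 10, precision_z = 20,
                            precision_cv = 0.25, min_separation = 0) {
  if (!is.null(tau_on) && !is.null(lambda)) {
    derived <- tau_on / (1 - exp(-1 / lambda))
    if (!is.null(locs_per_dye_mean) &&
        abs(derived - locs_per_dye_mean) > 1e-9 * abs(locs_per_dye_mean))
      stop("tau_on/(1 - exp(-1/lambda)) = ", derived,
           " conflicts with locs_per_dye_mean = ", locs_per_dye_mean)
    locs_per_dye_mean <- derived
  }
  locs_per_dye_mean <- locs_per_dye_mean %||% 10
  stopifnot(n_clusters >= 0, radius_mean > 0, radius_sd >= 0, dyes_mean > 0,
            locs_per_dye_mean >= 1, precision_xy > 0, precision_z > 0,
            precision_cv >= 0, min_separation >= 0)
  structure(list(n_clusters = as.integer(n_clusters),
                 radius_mean = radius_mean, radius_sd = radius_sd,
                 dyes_mean = dyes_mean,
                 locs_per_dye_mean = locs_per_dye_mean,
                 tau_on = tau_on, lambda = lambda,
                 precision_xy = precision_xy, precision_z = precision_z,
                 precision_cv = precision_cv,
                 min_separation = min_separation),
            class = "smlm_population")
}

#' Standard simulation presets
#'
#' The benchmark conditions used throughout the package: single populations
#' of 100 clusters with mean radii 80, 60 or 40 nm (sd 20% of the mean), dye
#' means 20, 20 and 10 respectively, blink mean 10, precisions 10 nm lateral
#' / 20 nm axial, and minimum centroid separations of 330, 310 and 290 nm;
#' and the mixed populations (50/50 two-way mixes totalling 100 clusters and
#' the 40/40/40 three-way mix totalling 120) with a 250 nm separation. The
#' simulation volume gives approximately one cluster per cubic micron.
#'
#' @param name One of `"80nm"`, `"60nm"`, `"40nm"`, `"mix-40-80"`,
#'   `"mix-60-80"`, `"mix-40-60-80"`.
#' @return A list of `smlm_population` objects (attribute `min_separation`
#'   carries the applicable global centroid separation).
#' @export
smlm_preset <- function(name = c("80nm", "60nm", "40nm", "mix-40-80",
                                 "mix-60-80", "mix-40-60-80")) {
  name <- match.arg(name)
  p80 <- function(n, sep) smlm_population(n, 80, 16, 20, 10,
                                          min_separation = sep)
  p60 <- function(n, sep) smlm_population(n, 60, 12, 20, 10,
                                          min_separation = sep)
  p40 <- function(n, sep) smlm_population(n, 40, 8, 10, 10,
                                          min_separation = sep)
  pops <- switch(name,
    "80nm" = list(p80(100L, 330)),
    "60nm" = list(p60(100L, 310)),
    "40nm" = list(p40(100L, 290)),
    "mix-40-80" = list(p40(50L, 250), p80(50L, 250)),
    "mix-60-80" = list(p60(50L, 250), p80(50L, 250)),
    "mix-40-60-80" = list(p40(40L, 250), p60(40L, 250), p80(40L, 250)))
  attr(pops, "preset") <- name
  pops
}

#' Place cluster centroids with a minimum separation
#'
#' Uniformly positions `n` centroids in the box subject to all pairwise
#' distances being at least `min_separation` (sequential rejection sampling).
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param n Number of centroids.
#' @param box 2x3 matrix `rbind(lower, upper)` (nm).
#' @param min_separation Minimum pairwise centroid distance (nm); 0 gives
#'   unconstrained uniform sampling.
#' @param max_attempts Maximum rejection draws per centroid before declaring
#'   the packing infeasible.
#' @return An n x 3 matrix of centroid coordinates.
#' @export
place_centroids <- function(n, box, min_separation = 0, max_attempts = 10000L) {
  n <- as.integer(n)
  if (n == 0L) return(matrix(numeric(0), 0L, 3L))
  box <- as.matrix(box)
  out <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      p <- c(runif(1, box[1, 1], box[2, 1]),
             runif(1, box[1, 2], box[2, 2]),
             runif(1, box[1, 3], box[2, 3]))
      if (i == 1L || min_separation <= 0) { placed <- TRUE }
      else {
        prev <- out[seq_len(i - 1L), , drop = FALSE]
        d2 <- (prev[, 1] - p[1])^2 + (prev[, 2] - p[2])^2 + (prev[, 3] - p[3])^2
        placed <- all(d2 >= min_separation^2)
      }
      if (placed) { out[i, ] <- p; break }
    }
    if (!placed)
      stop("could not place ", n, " centroids at min_separation = ",
           min_separation, " nm in the given box (packing density too high; ",
           "volume = ", prod(box[2, ] - box[1, ]), " nm^3)")
  }
  out
}

# uniform points in a sphere of radius r centred at the origin
runif_sphere <- function(n, r) {
  if (n == 0L) return(matrix(numeric(0), 0L, 3L))
  u <- matrix(rnorm(3L * n), n, 3L)
  u <- u / sqrt(rowSums(u^2))
  u * (r * runif(n)^(1 / 3))
}

# per-localization precision widths: log-normal with given mean and CV
r_precision <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# one cluster: dyes uniform in the sphere, geometric blink counts (mean m,
# support 1, 2, ...), anisotropic Gaussian scatter about each dye
simulate_cluster <- function(centroid, radius, spec) {
  n_dyes <- rpois(1L, spec$dyes_mean)
  dyes <- runif_sphere(n_dyes, radius)
  if (n_dyes == 0L) {
    return(list(locs = matrix(numeric(0), 0L, 3L),
                dyes = dyes, n_dyes = 0L))
  }
  blinks <- 1L + rgeom(n_dyes, prob = 1 / spec$locs_per_dye_mean)
  nl <- sum(blinks)
  dye_of <- rep(seq_len(n_dyes), blinks)
  sxy <- r_precision(nl, spec$precision_xy, spec$precision_cv)
  sz <- r_precision(nl, spec$precision_z, spec$precision_cv)
  locs <- dyes[dye_of, , drop = FALSE] +
    cbind(rnorm(nl, 0, sxy), rnorm(nl, 0, sxy), rnorm(nl, 0, sz))
  locs <- sweep(locs, 2L, -centroid)  # translate to centroid
  list(locs = locs, dyes = sweep(dyes, 2L, -centroid), n_dyes = n_dyes)
}

# expected per-cluster localization count and volume, pooled over populations
# (weighted by cluster counts); E[R^3] for a Gaussian radius law is
# mu^3 + 3 mu sd^2 (truncation at zero is negligible at the presets' CV)
pooled_cluster_stats <- function(populations) {
  n <- vapply(populations, function(p) as.numeric(p$n_clusters), 0)
  nbar <- vapply(populations, function(p) p$dyes_mean * p$locs_per_dye_mean, 0)
  vbar <- vapply(populations, function(p)
    4 / 3 * pi * (p$radius_mean^3 + 3 * p$radius_mean * p$radius_sd^2), 0)
  list(n_cluster = sum(n * nbar) / sum(n), v_cluster = sum(n * vbar) / sum(n))
}

#' Simulate a synthetic SMLM dataset with ground truth
#'
#' Generates a localization table with the statistical structure of the
#' package's benchmark simulations: well-separated spherical clusters (one or
#' more populations), Poisson dye counts, geometric blink counts,
#' anisotropic Gaussian localization scatter, and uniform background noise
#' whose amount is controlled by the dimensionless noise level `zeta` — the
#' ratio of the background localization density to the expected in-cluster
#' localization density:
#' \deqn{N_{noise} = round(\zeta \cdot (\bar N_{cluster}/\bar V_{cluster}) \cdot V_{sim})}
#' with the expected per-cluster count \eqn{\bar N_{cluster}} and mean cluster
#' volume \eqn{\bar V_{cluster}} pooled over populations (weighted by cluster
#' counts). At `zeta = 1` the background density equals the mean in-cluster
#' density.
#'
#' @param populations A single [smlm_population()], a list of them, or a
#'   [smlm_preset()] result.
#' @param zeta Noise level, `>= 0`. Default 0.
#' @param volume Optional 2x3 box (nm). Default: a cube whose volume in cubic
#'   microns equals the total number of clusters (approximately one cluster
#'   per cubic micron).
#' @param seed Integer RNG seed; the output is deterministic given the seed.
#' @param min_separation Minimum centroid separation (nm) applied across all
#'   populations; default: the maximum of the populations' own values.
#' @return An object of class `smlm_sim`: list with `locs` (data frame
#'   x/y/z nm), `truth` (integer labels, `-1` noise, `0..K-1` cluster ids),
#'   `clusters` (data frame: id, population, centroid, drawn radius, dye and
#'   localization counts), `dye_positions` (list of per-cluster matrices),
#'   `box`, `zeta`, `n_noise`, `seed`.
#' @examples
#' sim <- simulate_smlm(smlm_preset("80nm"), zeta = 0.01, seed = 1)
#' sim
#' @export
simulate_smlm <- function(populations, zeta = 0, volume = NULL, seed = 1L,
                          min_separation = NULL) {
  if (inherits(populations, "smlm_population")) populations <- list(populations)
  stopifnot(length(populations) > 0,
            all(vapply(populations, inherits, TRUE, "smlm_population")),
            zeta >= 0)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  n_total <- sum(vapply(populations, function(p) p$n_clusters, 0L))
  if (is.null(volume)) {
    side <- (max(1L, n_total) * 1e9)^(1 / 3)  # ~1 cluster per um^3
    volume <- rbind(c(0, 0, 0), rep(side, 3L))
  }
  volume <- as.matrix(volume)
  if (n_total == 0L && zeta == 0) {
    return(structure(list(locs = data.frame(x = numeric(0), y = numeric(0),
                                            z = numeric(0)),
                          truth = integer(0),
                          clusters = data.frame(),
                          dye_positions = list(), box = volume, zeta = zeta,
                          n_noise = 0L, seed = as.integer(seed),
                          populations = populations),
                     class = "smlm_sim"))
  }

  sep <- min_separation %||%
    max(vapply(populations, function(p) p$min_separation, 0))
  cents <- place_centroids(n_total, volume, sep)
  pop_of <- rep(seq_along(populations),
                vapply(populations, function(p) p$n_clusters, 0L))

  radii <- numeric(n_total)
  locs_list <- vector("list", n_total)
  dyes_list <- vector("list", n_total)
  n_dyes <- integer(n_total)
  for (k in seq_len(n_total)) {
    spec <- populations[[pop_of[k]]]
    r <- -1
    while (r <= 0) r <- rnorm(1L, spec$radius_mean, spec$radius_sd)
    radii[k] <- r
    cl <- simulate_cluster(cents[k, ], r, spec)
    locs_list[[k]] <- cl$locs
    dyes_list[[k]] <- cl$dyes
    n_dyes[k] <- cl$n_dyes
  }
  n_locs <- vapply(locs_list, nrow, 0L)
  locs <- do.call(rbind, locs_list)
  truth <- rep(seq_len(n_total) - 1L, n_locs)

  stats <- pooled_cluster_stats(populations)
  v_sim <- prod(volume[2L, ] - volume[1L, ])
  n_noise <- as.integer(round(zeta * stats$n_cluster / stats$v_cluster * v_sim))
  if (n_noise > 0L) {
    noise <- cbind(runif(n_noise, volume[1, 1], volume[2, 1]),
                   runif(n_noise, volume[1, 2], volume[2, 2]),
                   runif(n_noise, volume[1, 3], volume[2, 3]))
    locs <- rbind(locs, noise)
    truth <- c(truth, rep(-1L, n_noise))
  }
  locs <- as.data.frame(locs)
  names(locs) <- c("x", "y", "z")
  rownames(locs) <- NULL

  clusters <- data.frame(id = seq_len(n_total) - 1L,
                         population = pop_of,
                         centroid_x = cents[, 1L], centroid_y = cents[, 2L],
                         centroid_z = cents[, 3L],
                         radius = radii, n_dyes = n_dyes,
                         n_localizations = n_locs)
  structure(list(locs = locs, truth = truth, clusters = clusters,
                 dye_positions = dyes_list, box = volume, zeta = zeta,
                 n_noise = n_noise, seed = as.integer(seed),
                 populations = populations),
            class = "smlm_sim")
}

#' @export
print.smlm_sim <- function(x, ...) {
  cat("Synthetic SMLM dataset\n")
  cat(sprintf("  clusters: %d (%d population%s), zeta = %g\n",
              nrow(x$clusters), length(x$populations),
              if (length(x$populations) > 1) "s" else "", x$zeta))
  cat(sprintf("  localizations: %d clustered + %d noise = %d\n",
              sum(x$truth >= 0L), x$n_noise, nrow(x$locs)))
  side <- x$box[2L, ] - x$box[1L, ]
  cat(sprintf("  volume: %.0f x %.0f x %.0f nm (seed %d)\n",
              side[1], side[2], side[3], x$seed))
  invisible(x)
}

#' @export
plot.smlm_sim <- function(x, ...) {
  cols <- ifelse(x$truth == -1L, "grey80", "steelblue")
  graphics::plot(x$locs$x, x$locs$y, col = cols, pch = 16, cex = 0.3,
                 xlab = "x (nm)", ylab = "y (nm)",
                 main = sprintf("%d simulated clusters, zeta = %g",
                                nrow(x$clusters), x$zeta), ...)
  invisible(x)
}
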