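#' Complete-spatial-randomness surrogate of a localization table
#'
#' Generates an artificial localization table with the same number of points
#' as the input, each point positioned independently and uniformly within the
#' same volume (by default the data's tight axis-aligned bounding box). This
#' is the null model against which the density threshold minL is calibrated:
#' the optimal threshold is the lowest value at which the clustering returns
#' zero clusters on such randomly scattered data.
#'
#' @param table Localization table (see [as_localizations()]); must be
#'   non-empty.
#' @param seed Integer RNG seed; the surrogate is deterministic given the
#'   seed.
#' @param bounds Optional explicit 2x3 box (for cropped fields of view);
#'   default the data's bounding box.
#' @return A numeric n x 3 matrix of uniform coordinates in the box.
#' @export
csr_surrogate <- function(table, seed = 1L, bounds = NULL) {
  xyz <- as_localizations(table)
  n <- nrow(xyz)
  if (n == 0L) stop("cannot build a CSR surrogate of an empty table")
  if (is.null(bounds)) bounds <- rbind(apply(xyz, 2, min), apply(xyz, 2, max))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  out <- cbind(x = runif(n, bounds[1, 1], bounds[2, 1]),
               y = runif(n, bounds[1, 2], bounds[2, 2]),
               z = runif(n, bounds[1, 3], bounds[2, 3]))
  out
}

# --- cached clustering engine -------------------------------------------------
# Binning and enhancement depend only on (table, delta); candidate component
# sizes depend additionally on minL but not on minC (minC is a pure filter).
# The scan exploits both facts.

voxel_cache <- function(xyz, delta, bounds = NULL, connectivity = 6,
                        inclusive = TRUE, strict_edges = FALSE) {
  grid <- build_density_map(xyz, delta, bounds)
  edm <- enhance_density_map(grid)
  occ_lin <- which(edm$counts > 0L)
  enh_occ <- edm$enhanced[occ_lin]
  eligible <- rep(TRUE, length(occ_lin))
  if (strict_edges && length(occ_lin) > 0L)
    eligible <- interior_mask(edm$dims)[occ_lin]
  env <- new.env(parent = emptyenv())
  # the full arrays are dropped: per-minL work operates on occupied indices
  list(dims = edm$dims, occ_lin = occ_lin, enh_occ = enh_occ,
       eligible = eligible, connectivity = connectivity,
       inclusive = inclusive, memo = env,
       max_enhanced = max(0L, enh_occ))
}

# candidate (core+border) voxel counts at a given minL, memoized
cache_sizes <- function(cache, minL) {
  key <- as.character(minL)
  hit <- get0(key, envir = cache$memo)
  if (!is.null(hit)) return(hit)
  is_core <- cache$eligible &
    (if (cache$inclusive) cache$enh_occ >= minL else cache$enh_occ > minL)
  core_lin <- cache$occ_lin[is_core]
  border_lin <- integer(0)
  if (length(core_lin) > 0L && any(!is_core)) {
    nb <- unique(neighbour_pairs(core_lin, cache$dims, offsets_face)$to)
    hitocc <- match(nb, cache$occ_lin)
    nb <- nb[!is.na(hitocc)]
    hitocc <- hitocc[!is.na(hitocc)]
    border_lin <- sort(nb[!is_core[hitocc]])
  }
  vc <- candidates_from_index(core_lin, border_lin, cache$dims, minC = 1L,
                              connectivity = cache$connectivity,
                              sizes_only = TRUE)
  assign(key, vc$candidate_sizes, envir = cache$memo)
  vc$candidate_sizes
}

cache_nclusters <- function(cache, minL, minC) sum(cache_sizes(cache, minL) >= minC)

#' Select the optimal density threshold minL*
#'
#' The optimal density threshold is the lowest `minL` at which the clustering
#' returns zero clusters on a complete-spatial-randomness surrogate of the
#' data (same point count, uniform in the same volume), holding `delta` and
#' `minC` fixed. Chance aggregations on random data are subject to the same
#' `minC` size filter as the real analysis. With `replicates > 1`, every
#' surrogate must return zero clusters, which can only raise the threshold.
#'
#' @param table Localization table.
#' @param delta Grid spacing (nm).
#' @param minC Cluster-size threshold (voxels) under optimization.
#' @param minL_range Contiguous ascending integer range to search. Default
#'   `NULL`: 1 up to the maximum enhanced density on the surrogate (plus one),
#'   which guarantees termination.
#' @param seed RNG seed for the surrogate(s).
#' @param replicates Number of independent surrogates (default 1).
#' @param bounds,connectivity,inclusive,strict_edges Passed through to the
#'   clustering (see [focal3d()], [csr_surrogate()]).
#' @return A list of class `focal_minL`: `minL_star` (integer), `exhausted`
#'   (`TRUE` with a warning if no value in the range achieved zero clusters;
#'   the range maximum is returned), `delta`, `minC`, `seed`, `replicates`.
#' @export
optimize_minL <- function(table, delta, minC, minL_range = NULL, seed = 1L,
                          replicates = 1L, bounds = NULL, connectivity = 6,
                          inclusive = TRUE, strict_edges = FALSE) {
  xyz <- as_localizations(table)
  if (nrow(xyz) == 0L) stop("cannot optimize minL on an empty table")
  caches <- lapply(seq_len(replicates), function(r) {
    surr <- csr_surrogate(xyz, seed = as.integer(seed) + (r - 1L),
                          bounds = bounds)
    voxel_cache(surr, delta, bounds = bounds, connectivity = connectivity,
                inclusive = inclusive, strict_edges = strict_edges)
  })
  if (is.null(minL_range)) {
    hi <- max(1L, max(vapply(caches, function(cc) cc$max_enhanced, 0L)) + 1L)
    minL_range <- seq.int(1L, hi)
  }
  minL_range <- as.integer(minL_range)
  ans <- NA_integer_
  for (minL in minL_range) {
    zero <- all(vapply(caches, function(cc)
      cache_nclusters(cc, minL, minC) == 0L, TRUE))
    if (zero) { ans <- minL; break }
  }
  exhausted <- is.na(ans)
  if (exhausted) {
    warning("no minL in the searched range gave zero clusters on the ",
            "surrogate; returning the range maximum")
    ans <- max(minL_range)
  }
  structure(list(minL_star = ans, exhausted = exhausted, delta = delta,
                 minC = minC, seed = as.integer(seed),
                 replicates = as.integer(replicates)),
            class = "focal_minL")
}

#' @export
print.focal_minL <- function(x, ...) {
  cat(sprintf("minL* = %d (delta = %g nm, minC = %d, %d surrogate%s%s)\n",
              x$minL_star, x$delta, x$minC, x$replicates,
              if (x$replicates > 1) "s" else "",
              if (x$exhausted) "; range exhausted" else ""))
  invisible(x)
}

#' Parameter scan: cluster count vs minC across grid sizes
#'
#' For every combination of grid spacing `delta` and cluster-size threshold
#' `minC`, selects the optimal density threshold minL* against a
#' complete-spatial-randomness surrogate (see [optimize_minL()]) and counts
#' the clusters the algorithm then detects on the real data at
#' `(delta, minL*, minC)`. The resulting clusters-vs-minC curves are the
#' object a user inspects for plateaus — regions where the count is
#' insensitive to `minC` — near an optimal grid size; [find_plateau()]
#' formalizes that reading.
#'
#' One surrogate is drawn per (seed, delta) and shared across the minC values
#' of that grid size; the scan is bit-reproducible given (table, seed).
#'
#' @param table Localization table.
#' @param delta Vector of grid spacings (nm) to scan.
#' @param minC Ascending vector of cluster-size thresholds (voxels).
#' @param minL_max Optional cap on the minL search range.
#' @param seed RNG seed for the surrogates.
#' @param replicates Surrogate replicates per point (default 1).
#' @param bounds,connectivity,inclusive,strict_edges See [focal3d()].
#' @return An object of class `focal_scan`: data frame with columns `delta`,
#'   `minC`, `minL_star`, `n_clusters`, plus attributes `seed` and
#'   `replicates`.
#' @export
focal_scan <- function(table, delta, minC, minL_max = NULL, seed = 1L,
                       replicates = 1L, bounds = NULL, connectivity = 6,
                       inclusive = TRUE, strict_edges = FALSE) {
  xyz <- as_localizations(table)
  if (nrow(xyz) == 0L) stop("cannot scan an empty table")
  if (length(delta) == 0L || length(minC) == 0L)
    stop("`delta` and `minC` must be non-empty")
  minC <- as.integer(minC)
  if (is.unsorted(minC, strictly = TRUE))
    stop("`minC` values must be strictly increasing")
  rows <- vector("list", length(delta))
  for (di in seq_along(delta)) {
    d <- delta[di]
    seed_d <- as.integer(seed) + 10000L * (di - 1L)
    surr_caches <- lapply(seq_len(replicates), function(r) {
      surr <- csr_surrogate(xyz, seed = seed_d + (r - 1L), bounds = bounds)
      voxel_cache(surr, d, bounds = bounds, connectivity = connectivity,
                  inclusive = inclusive, strict_edges = strict_edges)
    })
    real_cache <- voxel_cache(xyz, d, bounds = bounds,
                              connectivity = connectivity,
                              inclusive = inclusive,
                              strict_edges = strict_edges)
    hi <- max(1L, max(vapply(surr_caches, function(cc) cc$max_enhanced, 0L)) + 1L)
    if (!is.null(minL_max)) hi <- min(hi, as.integer(minL_max))
    minL_star <- integer(length(minC))
    nclus <- integer(length(minC))
    for (ci in seq_along(minC)) {
      mc <- minC[ci]
      # linear scan from the bottom: candidate sizes are memoized per minL,
      # so re-scanning for each minC only re-reads cached size vectors
      ans <- NA_integer_
      for (minL in seq.int(1L, hi)) {
        zero <- all(vapply(surr_caches, function(cc)
          cache_nclusters(cc, minL, mc) == 0L, TRUE))
        if (zero) { ans <- minL; break }
      }
      if (is.na(ans)) ans <- hi
      minL_star[ci] <- ans
      nclus[ci] <- cache_nclusters(real_cache, ans, mc)
    }
    rows[[di]] <- data.frame(delta = d, minC = minC, minL_star = minL_star,
                             n_clusters = nclus)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, seed = as.integer(seed), replicates = as.integer(replicates),
            class = c("focal_scan", "data.frame"))
}

#' @export
print.focal_scan <- function(x, ...) {
  cat(sprintf("FOCAL3D parameter scan: %d grid size(s) x %d minC value(s), seed %d\n",
              length(unique(x$delta)), length(unique(x$minC)),
              attr(x, "seed")))
  print.data.frame(utils::head(as.data.frame(x), 12))
  if (nrow(x) > 12L) cat(sprintf("  ... %d more rows\n", nrow(x) - 12L))
  invisible(x)
}

#' Plot clusters-vs-minC curves of a parameter scan
#'
#' One curve per grid size delta, the visual on which plateau regions are
#' identified.
#'
#' @param x A `focal_scan` object.
#' @param target Optional horizontal reference line (e.g. a known cluster
#'   count in simulations).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.focal_scan <- function(x, target = NULL, ...) {
  ds <- unique(x$delta)
  pal <- grDevices::hcl.colors(max(3L, length(ds)), "Dark 3")
  graphics::plot(range(x$minC), range(x$n_clusters), type = "n",
                 xlab = "minC (voxels)", ylab = "clusters detected", ...)
  for (i in seq_along(ds)) {
    s <- x[x$delta == ds[i], ]
    graphics::lines(s$minC, s$n_clusters, col = pal[i], type = "b", pch = 16,
                    cex = 0.6)
  }
  if (!is.null(target))
    graphics::abline(h = target, col = "red", lty = 2)
  graphics::legend("topright", legend = sprintf("Δ = %g nm", ds),
                   col = pal[seq_along(ds)], lty = 1, pch = 16, bty = "n")
  invisible(x)
}

#' Identify plateau regions and recommend (delta*, minC*)
#'
#' For each grid size, finds the longest run of consecutive `minC` scan points
#' whose cluster counts agree within a relative tolerance (runs at zero
#' clusters are excluded). The recommended operating point is the grid size
#' with the longest such run, taking `minC*` at the cusp of the plateau (its
#' first point — the smallest minC after the curve's inflection) with the
#' minL* already selected there. Plateau identification mirrors the visual
#' procedure of reading clusters-vs-minC curves; the raw curves should always
#' be inspected alongside the recommendation.
#'
#' @param scan A [focal_scan()] result.
#' @param rel_tol Relative tolerance within a run: a run satisfies
#'   `(max - min) / max <= rel_tol`. Default 0.02.
#' @return An object of class `focal_plateau`: list with `runs` (per-delta
#'   data frame: delta, start/end minC, length, plateau cluster count),
#'   `delta_star`, `minC_star`, `minL_star`, `n_clusters` (count at the
#'   recommendation), and `flag` (`"ok"`, `"low-confidence"` when the best
#'   run has length 1, or `"no-recommendation"` for all-zero curves).
#' @export
find_plateau <- function(scan, rel_tol = 0.02) {
  stopifnot(inherits(scan, "focal_scan"))
  if (!(rel_tol > 0 && rel_tol < 1)) stop("`rel_tol` must be in (0, 1)")
  ds <- unique(scan$delta)
  runs <- lapply(ds, function(d) {
    s <- scan[scan$delta == d, ]
    s <- s[order(s$minC), ]
    best <- longest_run(s$n_clusters, rel_tol)
    if (is.null(best))
      return(data.frame(delta = d, minC_start = NA_integer_,
                        minC_end = NA_integer_, length = 0L,
                        n_clusters = NA_integer_, minL_star = NA_integer_))
    data.frame(delta = d,
               minC_start = s$minC[best[1L]], minC_end = s$minC[best[2L]],
               length = best[2L] - best[1L] + 1L,
               n_clusters = s$n_clusters[best[1L]],
               minL_star = s$minL_star[best[1L]])
  })
  runs <- do.call(rbind, runs)
  if (all(runs$length == 0L)) {
    return(structure(list(runs = runs, delta_star = NA_real_,
                          minC_star = NA_integer_, minL_star = NA_integer_,
                          n_clusters = NA_integer_,
                          flag = "no-recommendation", rel_tol = rel_tol),
                     class = "focal_plateau"))
  }
  ib <- which.max(runs$length)  # ties: first (smallest delta)
  flag <- if (runs$length[ib] <= 1L) "low-confidence" else "ok"
  structure(list(runs = runs,
                 delta_star = runs$delta[ib],
                 minC_star = runs$minC_start[ib],
                 minL_star = runs$minL_star[ib],
                 n_clusters = runs$n_clusters[ib],
                 flag = flag, rel_tol = rel_tol),
            class = "focal_plateau")
}

# longest maximal run [i, j] with (max-min)/max <= tol, excluding zero counts;
# returns c(i, j) or NULL. Two-pointer sweep with running min/max via
# recomputation on window shrink (windows are short; counts are small ints).
longest_run <- function(v, tol) {
  n <- length(v)
  best <- NULL; best_len <- 0L
  i <- 1L
  while (i <= n) {
    if (v[i] == 0L) { i <- i + 1L; next }
    j <- i
    lo <- v[i]; hi <- v[i]
    while (j < n && v[j + 1L] != 0L) {
      nlo <- min(lo, v[j + 1L]); nhi <- max(hi, v[j + 1L])
      if ((nhi - nlo) / nhi <= tol) { j <- j + 1L; lo <- nlo; hi <- nhi }
      else break
    }
    if (j - i + 1L > best_len) { best <- c(i, j); best_len <- j - i + 1L }
    i <- i + 1L
  }
  best
}

#' @export
print.focal_plateau <- function(x, ...) {
  cat("FOCAL3D plateau report (rel_tol =", x$rel_tol, ")\n")
  print.data.frame(x$runs)
  if (x$flag == "no-recommendation") {
    cat("  no plateau found (all-zero curves)\n")
  } else {
    cat(sprintf("  recommended: delta* = %g nm, minC* = %d, minL* = %d -> %d clusters [%s]\n",
                x$delta_star, x$minC_star, x$minL_star, x$n_clusters, x$flag))
  }
  invisible(x)
}
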