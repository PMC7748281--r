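#' Bin localizations onto a cubic voxel grid
#'
#' Discretizes a 3D localization table into cubic voxels of side `delta`,
#' producing the raw localization density map that the FOCAL3D clustering
#' pipeline operates on. Each localization is assigned to exactly one voxel by
#' `floor((coord - origin)/delta)` with half-open voxel intervals
#' `[k*delta, (k+1)*delta)`; points lying exactly on the global upper bound of
#' an axis fall in the last voxel of that axis.
#'
#' When `bounds` is omitted, the grid covers the tight bounding box of the
#' data, expanded so each axis spans an integer number of voxels; no point is
#' discarded. With explicit `bounds`, points outside the box are dropped (their
#' voxel index is `NA`).
#'
#' @param table A localization table: a data frame (or matrix) with columns
#'   `x`, `y`, `z` in nanometres, or anything accepted by
#'   [as_localizations()].
#' @param delta Grid spacing \eqn{\Delta} in nm (voxel side length), `> 0`.
#' @param bounds Optional 2x3 matrix `rbind(lower, upper)` of the analysis box
#'   in nm. Default: tight bounding box of the data.
#' @return An object of class `voxel_grid`: a list with elements `origin`
#'   (numeric 3), `delta`, `dims` (integer 3, voxels per axis), `counts` (3D
#'   integer array, localizations per voxel), `point_voxel` (integer vector,
#'   1-based linear voxel index per localization, `NA` if out of bounds) and
#'   `n_points`.
#' @seealso [enhance_density_map()], [focal3d()]
#' @examples
#' pts <- data.frame(x = runif(50, 0, 100), y = runif(50, 0, 100),
#'                   z = runif(50, 0, 100))
#' g <- build_density_map(pts, delta = 25)
#' sum(g$counts) == nrow(pts)
#' @export
build_density_map <- function(table, delta, bounds = NULL) {
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) || delta <= 0)
    stop("`delta` must be a single positive number (nm)")
  xyz <- as_localizations(table)
  n <- nrow(xyz)

  if (is.null(bounds)) {
    if (n == 0L) {
      bounds <- rbind(c(0, 0, 0), c(delta, delta, delta))
    } else {
      lo <- apply(xyz, 2L, min)
      hi <- apply(xyz, 2L, max)
      bounds <- rbind(lo, hi)
    }
    auto <- TRUE
  } else {
    bounds <- as.matrix(bounds)
    if (!all(dim(bounds) == c(2L, 3L)) || any(bounds[1L, ] > bounds[2L, ]))
      stop("`bounds` must be a 2x3 matrix rbind(lower, upper) with lower <= upper")
    auto <- FALSE
  }
  origin <- as.numeric(bounds[1L, ])
  span <- as.numeric(bounds[2L, ]) - origin
  dims <- pmax(1L, as.integer(ceiling(span / delta - 1e-9)))
  upper <- origin + dims * delta

  counts <- array(0L, dim = dims)
  point_voxel <- rep(NA_integer_, n)
  if (n > 0L) {
    iv <- matrix(NA_integer_, n, 3L)
    inb <- rep(TRUE, n)
    for (a in 1:3) {
      k <- floor((xyz[, a] - origin[a]) / delta)
      # points exactly on the global upper bound belong to the last voxel
      k[xyz[, a] >= upper[a] & xyz[, a] <= bounds[2L, a]] <- dims[a] - 1
      inb <- inb & k >= 0 & k <= dims[a] - 1
      iv[, a] <- as.integer(k)
    }
    if (auto && !all(inb)) stop("internal error: auto bounds dropped points")
    lin <- 1L + iv[, 1L] + dims[1L] * (iv[, 2L] + dims[2L] * iv[, 3L])
    lin[!inb] <- NA_integer_
    point_voxel <- lin
    tab <- tabulate(lin[!is.na(lin)], nbins = prod(dims))
    counts <- array(as.integer(tab), dim = dims)
  }

  structure(list(origin = origin, delta = delta, dims = dims,
                 counts = counts, point_voxel = point_voxel,
                 n_points = n),
            class = "voxel_grid")
}

# sum of the 3x3x3 neighbourhood by three separable 1D passes (zero padding)
nbr_sum_27 <- function(a) {
  d <- dim(a)
  r <- a
  if (d[1L] > 1L) {
    r[-1L, , ] <- r[-1L, , ] + a[-d[1L], , ]
    r[-d[1L], , ] <- r[-d[1L], , ] + a[-1L, , ]
  }
  a2 <- r
  if (d[2L] > 1L) {
    r[, -1L, ] <- r[, -1L, ] + a2[, -d[2L], ]
    r[, -d[2L], ] <- r[, -d[2L], ] + a2[, -1L, ]
  }
  a3 <- r
  if (d[3L] > 1L) {
    r[, , -1L] <- r[, , -1L] + a3[, , -d[3L]]
    r[, , -d[3L]] <- r[, , -d[3L]] + a3[, , -1L]
  }
  r
}

#' Contrast-enhanced density map
#'
#' Replaces the value of every occupied voxel with the sum of localization
#' counts over its 3x3x3 neighbourhood (27 voxels; out-of-grid neighbours
#' contribute zero). The enhancement is meaningful only for voxels that contain
#' at least one localization: empty voxels can never become core voxels
#' regardless of their neighbourhood sum.
#'
#' @param grid A `voxel_grid` from [build_density_map()].
#' @return The grid with an additional 3D integer array `enhanced` (the
#'   27-neighbourhood sums, stored for all voxels; consult `counts > 0` for
#'   eligibility), class `enhanced_density_map`/`voxel_grid`.
#' @examples
#' pts <- data.frame(x = 55, y = 55, z = 55)
#' e <- enhance_density_map(build_density_map(pts, 10))
#' e$enhanced[e$counts > 0]  # isolated voxel: sum equals its own count
#' @export
enhance_density_map <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  grid$enhanced <- nbr_sum_27(grid$counts)
  class(grid) <- unique(c("enhanced_density_map", class(grid)))
  grid
}

# interior mask: FALSE on the outermost voxel layer (strict edge mode)
interior_mask <- function(dims) {
  m <- array(TRUE, dim = dims)
  if (dims[1L] >= 1L) { m[1L, , ] <- FALSE; m[dims[1L], , ] <- FALSE }
  if (dims[2L] >= 1L) { m[, 1L, ] <- FALSE; m[, dims[2L], ] <- FALSE }
  if (dims[3L] >= 1L) { m[, , 1L] <- FALSE; m[, , dims[3L]] <- FALSE }
  m
}

#' Classify voxels as core or border
#'
#' Core voxels are occupied voxels whose enhanced density meets the threshold
#' `minL`; border voxels are occupied sub-threshold voxels that share a face
#' (6-connectivity) with at least one core voxel. The two masks are disjoint.
#'
#' @param edm An `enhanced_density_map` from [enhance_density_map()].
#' @param minL Density threshold (localizations), positive integer.
#' @param inclusive Logical; if `TRUE` (default) core requires
#'   `enhanced >= minL`, if `FALSE` strictly `>` . The published description
#'   of the threshold is ambiguous on this point; the inclusive form reads
#'   naturally with the surrogate-based definition of the optimal threshold.
#' @param strict_edges Logical; if `TRUE`, voxels on the outermost layer of
#'   the grid are ineligible as core (they may still be border). Default
#'   `FALSE`: neighbourhood sums are simply zero-padded so no localization is
#'   discarded.
#' @return A list of class `voxel_classes` with logical 3D arrays `core` and
#'   `border`, plus `dims`.
#' @export
classify_voxels <- function(edm, minL, inclusive = TRUE, strict_edges = FALSE) {
  stopifnot(inherits(edm, "enhanced_density_map"))
  if (!is.numeric(minL) || length(minL) != 1L || minL < 1)
    stop("`minL` must be a positive integer")
  core <- (edm$counts > 0L) &
    (if (inclusive) edm$enhanced >= minL else edm$enhanced > minL)
  if (strict_edges) core <- core & interior_mask(edm$dims)
  border <- array(FALSE, dim = edm$dims)
  core_lin <- which(core)
  if (length(core_lin) > 0L) {
    nb <- unique(neighbour_pairs(core_lin, edm$dims, offsets_face)$to)
    nb <- nb[edm$counts[nb] > 0L & !core[nb]]
    border[nb] <- TRUE
  }
  structure(list(core = core, border = border, dims = edm$dims),
            class = "voxel_classes")
}

# neighbour linear indices of linear voxel ids `lin` for a set of offsets;
# offsets is an integer matrix with columns (dx, dy, dz).
# Returns a list(from = ..., to = ...) keeping only in-bounds neighbours.
neighbour_pairs <- function(lin, dims, offsets) {
  nx <- dims[1L]; ny <- dims[2L]; nz <- dims[3L]
  z0 <- (lin - 1L) %/% (nx * ny)
  rem <- (lin - 1L) %% (nx * ny)
  y0 <- rem %/% nx
  x0 <- rem %% nx
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(offsets))) {
    x <- x0 + offsets[k, 1L]; y <- y0 + offsets[k, 2L]; z <- z0 + offsets[k, 3L]
    ok <- x >= 0L & x < nx & y >= 0L & y < ny & z >= 0L & z < nz
    if (any(ok)) {
      from <- c(from, lin[ok])
      to <- c(to, 1L + x[ok] + nx * (y[ok] + ny * z[ok]))
    }
  }
  list(from = from, to = to)
}

offsets_face <- rbind(c(1L, 0L, 0L), c(-1L, 0L, 0L),
                      c(0L, 1L, 0L), c(0L, -1L, 0L),
                      c(0L, 0L, 1L), c(0L, 0L, -1L))

offsets_26 <- {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  storage.mode(g) <- "integer"
  g[rowSums(abs(g)) > 0L, , drop = FALSE]
}

#' Extract candidate clusters from core/border masks
#'
#' Connected components of the core voxels (6-connectivity between faces by
#' default) form cluster skeletons; each border voxel is attached to exactly
#' one adjacent component — the one it shares the most faces with, remaining
#' ties going to the component with the smallest canonical index. Candidates
#' with fewer than `minC` total voxels (core + border) are discarded.
#' Retained clusters are numbered canonically by ascending minimum core-voxel
#' linear index (x-fastest ordering), starting at 0.
#'
#' @param classes A `voxel_classes` object from [classify_voxels()].
#' @param minC Minimum number of connected voxels for a candidate to count as
#'   a cluster; positive integer.
#' @param connectivity Core-core connectivity: 6 (faces, default) or 26.
#' @return A list of class `voxel_clusters`: `clusters` is a list of retained
#'   clusters, each a list with integer vectors `core` and `border` of linear
#'   voxel indices; `candidate_sizes` holds the (core+border) voxel counts of
#'   all candidates before the `minC` filter; `dims` the grid dimensions.
#' @export
extract_clusters <- function(classes, minC, connectivity = 6) {
  extract_clusters_impl(classes, minC, connectivity, sizes_only = FALSE)
}

# sizes_only skips the per-cluster voxel lists (used by the parameter scan,
# which only needs candidate sizes)
extract_clusters_impl <- function(classes, minC, connectivity = 6,
                                  sizes_only = FALSE) {
  stopifnot(inherits(classes, "voxel_classes"))
  if (!is.numeric(minC) || length(minC) != 1L || minC < 1)
    stop("`minC` must be a positive integer")
  if (!connectivity %in% c(6, 26)) stop("`connectivity` must be 6 or 26")
  dims <- classes$dims
  core_lin <- which(classes$core)
  border_lin <- which(classes$border)
  candidates_from_index(core_lin, border_lin, dims, minC, connectivity,
                        sizes_only = sizes_only)
}

# index-vector engine shared by the array API and the cached scan path;
# core_lin and border_lin are ascending linear voxel indices
candidates_from_index <- function(core_lin, border_lin, dims, minC,
                                  connectivity = 6, sizes_only = FALSE) {
  if (length(core_lin) == 0L) {
    return(structure(list(clusters = list(), candidate_sizes = integer(0),
                          dims = dims),
                     class = "voxel_clusters"))
  }
  off <- if (connectivity == 6) offsets_face else offsets_26
  # graph over core voxels; vertices indexed 1..ncore in core_lin order
  np <- neighbour_pairs(core_lin, dims, off)
  keep <- match(np$to, core_lin)
  ok <- !is.na(keep)
  gr <- igraph::make_empty_graph(n = length(core_lin), directed = FALSE)
  if (any(ok))
    gr <- igraph::add_edges(gr, rbind(match(np$from[ok], core_lin), keep[ok]))
  comp <- as.integer(igraph::components(gr)$membership)
  ncomp <- max(comp)

  # canonical component order: ascending minimum core-voxel linear index
  # (core_lin is ascending, so each component's first occurrence is its min)
  fcomp <- function(v) factor(v, levels = seq_len(ncomp))
  frst <- !duplicated(comp)
  minlin <- integer(ncomp)
  minlin[comp[frst]] <- core_lin[frst]
  comp <- as.integer(rank(minlin, ties.method = "first"))[comp]

  # border attachment: each border voxel goes to the adjacent component it
  # shares the most faces with; remaining ties to the smallest canonical id
  bp <- neighbour_pairs(core_lin, dims, offsets_face)  # border is face-defined
  is_b <- !is.na(match(bp$to, border_lin))
  bsizes <- integer(ncomp)
  border_of <- NULL
  if (any(is_b)) {
    bvox <- bp$to[is_b]
    bcomp <- comp[match(bp$from[is_b], core_lin)]
    o <- order(bvox, bcomp)
    bv <- bvox[o]; bc <- bcomp[o]
    nn <- length(bv)
    newrun <- c(TRUE, bv[-1L] != bv[-nn] | bc[-1L] != bc[-nn])
    faces <- tabulate(cumsum(newrun))           # faces per (voxel, comp) pair
    rv <- bv[newrun]; rc <- bc[newrun]
    o2 <- order(rv, -faces, rc)
    pick <- !duplicated(rv[o2])
    bx <- rv[o2][pick]; bax <- rc[o2][pick]
    bsizes <- tabulate(bax, nbins = ncomp)
    if (!sizes_only) border_of <- lapply(split(bx, fcomp(bax)), as.integer)
  }

  sizes <- tabulate(comp, nbins = ncomp) + bsizes
  if (sizes_only) {
    return(structure(list(clusters = list(), candidate_sizes = sizes,
                          dims = dims),
                     class = "voxel_clusters"))
  }
  if (is.null(border_of)) border_of <- rep(list(integer(0)), ncomp)
  core_of <- split(core_lin, fcomp(comp))
  keep_k <- which(sizes >= minC)
  clusters <- lapply(keep_k, function(k) {
    list(core = sort(core_of[[k]]), border = sort(border_of[[k]]))
  })
  structure(list(clusters = clusters, candidate_sizes = sizes, dims = dims),
            class = "voxel_clusters")
}
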