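# Brute-force reference implementations, deliberately independent of the
# package internals: per-point loops, triple-loop neighbourhood sums and a
# hand-written BFS flood fill.

oracle_bin <- function(xyz, origin, delta, dims) {
  counts <- array(0L, dim = dims)
  upper <- origin + dims * delta
  for (i in seq_len(nrow(xyz))) {
    k <- integer(3)
    for (a in 1:3) {
      k[a] <- floor((xyz[i, a] - origin[a]) / delta)
      if (xyz[i, a] == upper[a]) k[a] <- dims[a] - 1
    }
    if (all(k >= 0) && all(k <= dims - 1))
      counts[k[1] + 1, k[2] + 1, k[3] + 1] <-
        counts[k[1] + 1, k[2] + 1, k[3] + 1] + 1L
  }
  counts
}

oracle_nbr27 <- function(counts) {
  d <- dim(counts)
  out <- array(0L, dim = d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    s <- 0L
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] &&
          kk >= 1 && kk <= d[3])
        s <- s + counts[ii, jj, kk]
    }
    out[i, j, k] <- s
  }
  out
}

oracle_classify <- function(counts, enhanced, minL, inclusive = TRUE) {
  d <- dim(counts)
  core <- array(FALSE, dim = d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    core[i, j, k] <- counts[i, j, k] > 0 &&
      (if (inclusive) enhanced[i, j, k] >= minL else enhanced[i, j, k] > minL)
  border <- array(FALSE, dim = d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (core[i, j, k] || counts[i, j, k] == 0) next
    for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
      ii <- i + o[1]; jj <- j + o[2]; kk <- k + o[3]
      if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] &&
          kk >= 1 && kk <= d[3] && core[ii, jj, kk]) {
        border[i, j, k] <- TRUE
        break
      }
    }
  }
  list(core = core, border = border)
}

# BFS flood fill over TRUE voxels; returns integer array, 0 = background,
# components numbered in canonical order (ascending min linear index)
oracle_components <- function(mask, connectivity = 6) {
  d <- dim(mask)
  offs <- if (connectivity == 6) {
    list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1),
         c(0, 0, -1))
  } else {
    g <- expand.grid(-1:1, -1:1, -1:1)
    g <- g[rowSums(abs(g)) > 0, ]
    lapply(seq_len(nrow(g)), function(r) as.numeric(g[r, ]))
  }
  lab <- array(0L, dim = d)
  nextid <- 0L
  for (lin in which(mask)) {                 # ascending linear index
    if (lab[lin] != 0L) next
    nextid <- nextid + 1L
    queue <- lin
    lab[lin] <- nextid
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]
      ijk <- arrayInd(cur, d)
      for (o in offs) {
        p <- ijk + o
        if (any(p < 1) || any(p > d)) next
        plin <- p[1] + d[1] * ((p[2] - 1) + d[2] * (p[3] - 1))
        if (mask[plin] && lab[plin] == 0L) {
          lab[plin] <- nextid
          queue <- c(queue, plin)
        }
      }
    }
  }
  lab
}

oracle_ripley_count <- function(xyz, r) {
  n <- nrow(xyz)
  cnt <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= r) cnt <- cnt + 1L
  }
  cnt
}

# hand-crafted voxel_classes (masks set directly) isolate the attachment rule
make_classes <- function(dims, core_ijk, border_ijk) {
  core <- array(FALSE, dim = dims); border <- array(FALSE, dim = dims)
  for (v in core_ijk) core[v[1], v[2], v[3]] <- TRUE
  for (v in border_ijk) border[v[1], v[2], v[3]] <- TRUE
  structure(list(core = core, border = border, dims = as.integer(dims)),
            class = "voxel_classes")
}

random_table <- function(n, side = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cbind(x = runif(n, 0, side), y = runif(n, 0, side), z = runif(n, 0, side))
}
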