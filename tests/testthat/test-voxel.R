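test_that("binning matches a brute-force per-point oracle and conserves counts", {
  set.seed(101)
  for (rep in 1:3) {
    xyz <- random_table(1000, side = 100)
    g <- build_density_map(xyz, delta = 10)
    expect_equal(sum(g$counts), 1000L)
    expect_identical(g$counts,
                     oracle_bin(xyz, g$origin, g$delta, g$dims))
    # point_voxel is consistent with counts
    expect_equal(as.integer(tabulate(g$point_voxel, nbins = prod(g$dims))),
                 as.integer(g$counts))
  }
})

test_that("binning edge cases: empty table, single point, upper boundary", {
  g0 <- build_density_map(data.frame(x = numeric(0), y = numeric(0),
                                     z = numeric(0)), delta = 10)
  expect_equal(sum(g0$counts), 0L)

  g1 <- build_density_map(cbind(5, 5, 5), delta = 10,
                          bounds = rbind(c(0, 0, 0), c(30, 30, 30)))
  expect_equal(g1$counts[1, 1, 1], 1L)
  expect_equal(sum(g1$counts), 1L)

  # a point exactly on the global upper bound falls in the last voxel
  g2 <- build_density_map(rbind(c(0, 0, 0), c(30, 30, 30)), delta = 10,
                          bounds = rbind(c(0, 0, 0), c(30, 30, 30)))
  expect_equal(g2$counts[3, 3, 3], 1L)
  expect_equal(sum(g2$counts), 2L)

  expect_error(build_density_map(cbind(1, 1, 1), delta = 0), "delta")
  expect_error(build_density_map(cbind(1, 1, 1), delta = -5), "delta")
})

test_that("auto-derived bounds never drop points", {
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(1:500, 1)
    xyz <- random_table(n, side = runif(1, 1, 1000))
    g <- build_density_map(xyz, delta = runif(1, 0.5, 50))
    expect_equal(sum(g$counts), n)
    expect_false(anyNA(g$point_voxel))
  }
})

test_that("enhanced density map equals the triple-loop 27-neighbourhood oracle", {
  set.seed(42)
  counts <- array(rpois(20^3, 0.3), dim = c(20, 20, 20))
  g <- structure(list(origin = c(0, 0, 0), delta = 1, dims = c(20L, 20L, 20L),
                      counts = counts, point_voxel = integer(0),
                      n_points = sum(counts)),
                 class = "voxel_grid")
  e <- enhance_density_map(g)
  o <- oracle_nbr27(counts)
  nz <- counts > 0
  expect_equal(e$enhanced[nz], o[nz])
})

test_that("enhancement limit cases: isolated voxel and uniform grid", {
  a <- array(0L, dim = c(5, 5, 5)); a[3, 3, 3] <- 7L
  g <- structure(list(origin = c(0, 0, 0), delta = 1, dims = c(5L, 5L, 5L),
                      counts = a, point_voxel = integer(0), n_points = 7L),
                 class = "voxel_grid")
  expect_equal(enhance_density_map(g)$enhanced[3, 3, 3], 7L)

  u <- array(1L, dim = c(5, 5, 5))
  gu <- structure(list(origin = c(0, 0, 0), delta = 1, dims = c(5L, 5L, 5L),
                       counts = u, point_voxel = integer(0), n_points = 125L),
                  class = "voxel_grid")
  eu <- enhance_density_map(gu)
  expect_equal(eu$enhanced[3, 3, 3], 27L)  # interior: full neighbourhood
  expect_equal(eu$enhanced[1, 1, 1], 8L)   # corner: zero-padded
})

test_that("core/border classification matches the per-voxel oracle", {
  set.seed(13)
  for (rep in 1:4) {
    counts <- array(rpois(12^3, 0.4), dim = c(12, 12, 12))
    g <- structure(list(origin = c(0, 0, 0), delta = 1,
                        dims = c(12L, 12L, 12L), counts = counts,
                        point_voxel = integer(0), n_points = sum(counts)),
                   class = "voxel_grid")
    e <- enhance_density_map(g)
    minL <- sample(2:8, 1)
    cls <- classify_voxels(e, minL)
    o <- oracle_classify(counts, e$enhanced, minL)
    expect_identical(cls$core, o$core)
    expect_identical(cls$border, o$border)
    expect_false(any(cls$core & cls$border))  # masks disjoint
  }
})

test_that("border voxels require face adjacency, not diagonal adjacency", {
  # one hot voxel at the centre; its 6 face neighbours occupied subthreshold;
  # 2 diagonal neighbours also occupied
  counts <- array(0L, dim = c(5, 5, 5))
  counts[3, 3, 3] <- 20L
  for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1)))
    counts[3 + o[1], 3 + o[2], 3 + o[3]] <- 1L
  counts[2, 2, 3] <- 1L  # edge-diagonal neighbour
  counts[2, 2, 2] <- 1L  # corner-diagonal neighbour
  g <- structure(list(origin = c(0, 0, 0), delta = 1, dims = c(5L, 5L, 5L),
                      counts = counts, point_voxel = integer(0),
                      n_points = sum(counts)),
                 class = "voxel_grid")
  cls <- classify_voxels(enhance_density_map(g), minL = 28)
  expect_equal(sum(cls$core), 1L)
  expect_true(cls$core[3, 3, 3])
  expect_equal(sum(cls$border), 6L)
  expect_false(cls$border[2, 2, 3])
  expect_false(cls$border[2, 2, 2])
})

test_that("subthreshold grid yields empty masks", {
  counts <- array(1L, dim = c(4, 4, 4))
  g <- structure(list(origin = c(0, 0, 0), delta = 1, dims = c(4L, 4L, 4L),
                      counts = counts, point_voxel = integer(0),
                      n_points = 64L),
                 class = "voxel_grid")
  cls <- classify_voxels(enhance_density_map(g), minL = 100)
  expect_equal(sum(cls$core), 0L)
  expect_equal(sum(cls$border), 0L)
})

test_that("connected components match the BFS flood-fill oracle", {
  set.seed(23)
  for (connectivity in c(6, 26)) {
    for (rep in 1:4) {
      core <- array(runif(10^3) < 0.25, dim = c(10, 10, 10))
      cls <- structure(list(core = core,
                            border = array(FALSE, dim = c(10, 10, 10)),
                            dims = c(10L, 10L, 10L)),
                       class = "voxel_classes")
      vc <- extract_clusters(cls, minC = 1, connectivity = connectivity)
      lab <- oracle_components(core, connectivity)
      expect_equal(length(vc$clusters), max(lab))
      for (k in seq_along(vc$clusters))
        expect_identical(vc$clusters[[k]]$core, which(lab == k))
    }
  }
})

test_that("minC filters candidates by core+border voxel count", {
  # centre voxel of count 50 with two opposite-face neighbours of count 1:
  # enhanced(centre) = 52, enhanced(+-x) = 51, so minL = 52 gives one core
  # voxel with 2 attached border voxels -> candidate of 3 voxels
  counts <- array(0L, dim = c(5, 5, 5))
  counts[3, 3, 3] <- 50L
  counts[2, 3, 3] <- 1L; counts[4, 3, 3] <- 1L
  g <- structure(list(origin = c(0, 0, 0), delta = 1, dims = c(5L, 5L, 5L),
                      counts = counts, point_voxel = integer(0),
                      n_points = sum(counts)),
                 class = "voxel_grid")
  cls <- classify_voxels(enhance_density_map(g), minL = 52)
  expect_equal(sum(cls$core), 1L)
  expect_equal(sum(cls$border), 2L)
  expect_equal(length(extract_clusters(cls, minC = 3)$clusters), 1L)
  expect_equal(extract_clusters(cls, minC = 3)$candidate_sizes, 3L)
  expect_equal(length(extract_clusters(cls, minC = 4)$clusters), 0L)
  # no core voxels -> no clusters at any minC
  cls0 <- classify_voxels(enhance_density_map(g), minL = 100)
  expect_equal(length(extract_clusters(cls0, minC = 1)$clusters), 0L)
})

test_that("border tie-break: most shared faces wins, then smallest canonical id", {
  # tie on faces: border voxel flanked by two single-voxel components joins
  # the one with the smaller canonical (min linear) index
  cls <- make_classes(c(5, 3, 3),
                      core_ijk = list(c(1, 2, 2), c(3, 2, 2)),
                      border_ijk = list(c(2, 2, 2)))
  vc <- extract_clusters(cls, minC = 1)
  expect_equal(length(vc$clusters), 2L)
  lin <- function(i, j, k, d = c(5L, 3L, 3L))
    i + d[1] * ((j - 1) + d[2] * (k - 1))
  expect_equal(vc$clusters[[1]]$core, lin(1, 2, 2))
  expect_equal(vc$clusters[[1]]$border, lin(2, 2, 2))
  expect_equal(length(vc$clusters[[2]]$border), 0L)

  # more faces beats smaller id: an L-shaped component shares 2 faces with
  # the border voxel, a single-voxel component (smaller min index) shares 1
  cls2 <- make_classes(c(5, 5, 3),
                       core_ijk = list(c(2, 3, 2),              # B: 1 face
                                       c(4, 3, 2), c(4, 4, 2),  # A: L-shape
                                       c(3, 4, 2)),             # A: 2nd face
                       border_ijk = list(c(3, 3, 2)))
  vc2 <- extract_clusters(cls2, minC = 1)
  expect_equal(length(vc2$clusters), 2L)
  nb <- vapply(vc2$clusters, function(cl) length(cl$border), 0L)
  # component 1 (min lin: (2,3,2)) loses despite the smaller id
  expect_equal(nb, c(0L, 1L))
})

test_that("strict edge mode makes the outermost voxel layer ineligible as core", {
  counts <- array(5L, dim = c(4, 4, 4))
  g <- structure(list(origin = c(0, 0, 0), delta = 1, dims = c(4L, 4L, 4L),
                      counts = counts, point_voxel = integer(0),
                      n_points = sum(counts)),
                 class = "voxel_grid")
  e <- enhance_density_map(g)
  cls <- classify_voxels(e, minL = 1, strict_edges = TRUE)
  # only the 2x2x2 interior can be core
  expect_equal(sum(cls$core), 8L)
  expect_true(all(focal3d:::interior_mask(c(4L, 4L, 4L))[cls$core]))
  # edge voxels remain eligible as border
  expect_gt(sum(cls$border), 0L)
})

test_that("inclusive flag pins the threshold comparison", {
  counts <- array(0L, dim = c(3, 3, 3))
  counts[2, 2, 2] <- 10L
  g <- structure(list(origin = c(0, 0, 0), delta = 1, dims = c(3L, 3L, 3L),
                      counts = counts, point_voxel = integer(0),
                      n_points = 10L),
                 class = "voxel_grid")
  e <- enhance_density_map(g)
  expect_equal(sum(classify_voxels(e, 10, inclusive = TRUE)$core), 1L)
  expect_equal(sum(classify_voxels(e, 10, inclusive = FALSE)$core), 0L)
})
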