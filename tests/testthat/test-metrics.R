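test_that("confusion report matches hand-enumerated cases and identities", {
  # perfect labels
  r <- confusion_report(c(0L, 0L, 1L, -1L), c(5L, 5L, 2L, -1L))
  expect_equal(r$precision, 1)
  expect_equal(r$recall, 1)
  expect_equal(r$f1, 1)

  # all-noise prediction with true clustered points
  r2 <- confusion_report(rep(-1L, 4), c(0L, 0L, -1L, 1L))
  expect_equal(r2$recall, 0)
  expect_equal(r2$f1, 0)

  # truth: 10 clustered + 5 noise; prediction marks 8 clustered points and
  # 2 noise points as clustered -> TP 8, FP 2, FN 2 -> P = R = F1 = 0.8
  truth <- c(rep(0L, 10), rep(-1L, 5))
  pred <- c(rep(0L, 8), rep(-1L, 2), rep(0L, 2), rep(-1L, 3))
  r3 <- confusion_report(pred, truth)
  expect_equal(r3$TP, 8L); expect_equal(r3$FP, 2L); expect_equal(r3$FN, 2L)
  expect_equal(r3$precision, 0.8)
  expect_equal(r3$recall, 0.8)
  expect_equal(r3$f1, 0.8)
  # identities
  expect_equal(r3$TP + r3$FP + r3$FN + r3$TN, length(truth))
  expect_equal(r3$f1, 2 * r3$precision * r3$recall / (r3$precision + r3$recall))

  # cluster identity is ignored: same binary outcome under relabeling
  r4 <- confusion_report(pred + (pred >= 0L) * 7L, truth)
  expect_equal(r4$f1, r3$f1)

  expect_error(confusion_report(1:3, 1:4), "length")
})

test_that("degenerate confusion conventions: no true positives possible", {
  r <- confusion_report(c(-1L, 0L), c(-1L, -1L))
  expect_equal(r$recall, 1)
  expect_equal(r$flag, "no-true-positives-possible")
})

test_that("silhouette limit cases: coincident clusters and d_C = d_NN", {
  # two coincident-point clusters separated by d > 0: d_C = 0 -> S_C = 1
  tab <- rbind(matrix(rep(c(0, 0, 0), 5), ncol = 3, byrow = TRUE),
               matrix(rep(c(100, 0, 0), 5), ncol = 3, byrow = TRUE))
  lab <- rep(0:1, each = 5)
  s <- silhouette_score(lab, tab)
  expect_equal(s$score, 1)

  # engineered d_C = d_NN -> S_C = 0: centroid distance 100; make the mean
  # intra-cluster pairwise distance also 100 (pairs of points 200 apart in
  # clusters of 2: mean pairwise distance = 200... use centroid definition)
  tab2 <- rbind(c(-50, 0, 0), c(50, 0, 0), c(50, 0, 0), c(150, 0, 0))
  lab2 <- c(0L, 0L, 1L, 1L)
  # centroids at 0 and 100 -> d_NN = 100; member-to-centroid distance 50
  s2 <- silhouette_score(lab2, tab2, intra = "centroid")
  expect_equal(s2$score, (100 - 50) / 100)
  # pairwise definition on the same data: mean pairwise distance = 100
  s3 <- silhouette_score(lab2, tab2, intra = "pairwise")
  expect_equal(s3$score, 0)

  expect_error(silhouette_score(rep(0L, 5), matrix(rnorm(15), 5)), "2 clusters")
})

test_that("silhouette is <= 1 and rises as clusters tighten", {
  set.seed(71)
  make <- function(sigma) {
    cents <- rbind(c(0, 0, 0), c(500, 0, 0), c(0, 500, 0), c(250, 250, 400))
    tab <- do.call(rbind, lapply(1:4, function(k)
      cbind(rnorm(50, cents[k, 1], sigma), rnorm(50, cents[k, 2], sigma),
            rnorm(50, cents[k, 3], sigma))))
    silhouette_score(rep(0:3, each = 50), tab)$score
  }
  tight <- make(10); loose <- make(60)
  expect_lte(tight, 1)
  expect_lte(loose, 1)
  expect_gt(tight, loose)
})

test_that("hull volume: cube corners, degenerate sets, sphere convergence", {
  corners <- as.matrix(expand.grid(c(0, 2), c(0, 2), c(0, 2)))
  h <- hull_radius(corners)
  expect_equal(h$volume, 8, tolerance = 1e-12)
  expect_equal(h$effective_radius, (6 / pi)^(1 / 3), tolerance = 1e-12)
  expect_false(h$degenerate)

  # interior points do not change the hull
  set.seed(73)
  inner <- matrix(runif(300, 0.1, 1.9), ncol = 3)
  expect_equal(hull_radius(rbind(corners, inner))$volume, 8,
               tolerance = 1e-12)

  # fewer than 4 points or coplanar -> flagged
  expect_true(hull_radius(matrix(rnorm(9), 3))$degenerate)
  flat <- cbind(runif(20), runif(20), 0.5)
  expect_true(hull_radius(flat)$degenerate)
  collinear <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_true(hull_radius(collinear)$degenerate)

  # 1e4 uniform points in a sphere of radius 80: hull -> sphere
  set.seed(79)
  sph <- focal3d:::runif_sphere(1e4, 80)
  expect_equal(hull_radius(sph)$effective_radius, 80, tolerance = 0.05)
})

test_that("hull volume equals a Monte Carlo estimate on a random polytope", {
  # independent check: rejection-sample the hull volume of a random point set
  set.seed(83)
  pts <- matrix(rnorm(60), ncol = 3)
  v <- hull_radius(pts)$volume
  # Monte Carlo: fraction of box points inside the hull, via linear
  # programming-free test (point is in hull if it is in some tetra of a
  # Delaunay-free cover is hard; use the support-function test instead):
  # a point q is outside the hull iff some direction separates it; sample
  # many directions and compare max projections.
  box_lo <- apply(pts, 2, min); box_hi <- apply(pts, 2, max)
  nmc <- 20000
  q <- cbind(runif(nmc, box_lo[1], box_hi[1]),
             runif(nmc, box_lo[2], box_hi[2]),
             runif(nmc, box_lo[3], box_hi[3]))
  dirs <- matrix(rnorm(3 * 600), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  proj_max <- apply(dirs %*% t(pts), 1, max)      # support of hull
  inside <- rep(TRUE, nmc)
  pq <- dirs %*% t(q)
  for (d in seq_len(nrow(dirs)))
    inside <- inside & (pq[d, ] <= proj_max[d] + 1e-9)
  v_mc <- mean(inside) * prod(box_hi - box_lo)
  # the direction test only over-approximates the hull; 600 directions keep
  # the bias small for a 20-point cloud
  expect_equal(v, v_mc, tolerance = 0.1)
})

test_that("Ripley K matches the exhaustive pair-count oracle", {
  set.seed(89)
  xyz <- random_table(100, side = 50)
  box <- rbind(c(0, 0, 0), c(50, 50, 50))
  radii <- seq(2, 40, by = 2)
  rc <- ripley_k(xyz, radii, box = box)
  V <- 50^3
  n <- 100
  for (i in seq_along(radii)) {
    cnt <- oracle_ripley_count(xyz, radii[i])
    expect_equal(rc$K[i], V * cnt / (n * (n - 1)))
  }
  expect_true(all(diff(rc$K) >= 0))  # K non-decreasing
})

test_that("CSR null: H stays inside a seeded Monte Carlo envelope around 0", {
  box <- rbind(c(0, 0, 0), c(1000, 1000, 1000))
  radii <- seq(10, 200, by = 10)
  # envelope from 20 seeded CSR replicates
  Hs <- sapply(1:20, function(s) {
    set.seed(400 + s)
    ripley_k(random_table(2000, side = 1000), radii, box = box)$H
  })
  env <- apply(abs(Hs), 1, max)
  set.seed(500)
  H0 <- ripley_k(random_table(2000, side = 1000), radii, box = box)$H
  expect_true(all(abs(H0) <= pmax(env, 10)))
  # |H| small relative to the r-range
  expect_lt(max(abs(H0)), 0.15 * max(radii))
})

test_that("H peaks near the generative cluster scale on clustered data", {
  sim <- simulate_smlm(smlm_population(30, 80, 16, 20, 10,
                                       min_separation = 330), seed = 91)
  rc <- ripley_k(sim$locs, seq(10, 400, by = 10), box = sim$box,
                 max_points = 4000)
  r_peak <- attr(rc, "r_peak")
  expect_gt(r_peak, 40)   # within a factor of 2 of R_c = 80
  expect_lt(r_peak, 160)
  expect_error(ripley_k(cbind(1, 1, 1), 1:10), "2 points")
})

test_that("per-cluster radii diagnose merging and recover the generative scale", {
  sim <- simulate_smlm(smlm_preset("80nm"), zeta = 0.01, seed = 93)
  fit <- focal3d(sim$locs, delta = 40, minL = 9, minC = 10)
  cr <- cluster_radii(fit)
  expect_equal(nrow(cr), nrow(fit$clusters))
  ok <- is.finite(cr$effective_radius)
  expect_gt(mean(ok), 0.9)
  # mode of the recovered radius distribution within 25% of the mean radius
  expect_lt(abs(median(cr$effective_radius[ok]) - 80) / 80, 0.25)

  # constructed merge: two near clusters at an oversized grid fuse into one
  # candidate whose effective radius exceeds both generative radii
  set.seed(95)
  c1 <- sweep(focal3d:::runif_sphere(300, 40), 2, -c(500, 500, 500))
  c2 <- sweep(focal3d:::runif_sphere(300, 40), 2, -c(650, 500, 500))
  fit2 <- focal3d(rbind(c1, c2), delta = 150, minL = 1, minC = 1)
  expect_equal(nrow(fit2$clusters), 1L)
  r2 <- cluster_radii(fit2)$effective_radius
  expect_gt(r2, 40)
})
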