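test_that("hexagonal lattices reproduce the closed-form metrics", {
  r <- roi(c(50, 50), c(200, 200))
  for (s in c(5, 8, 10, 12)) {
    d <- spacing_to_density(s)
    mos <- generate_mosaic(d, c(300, 300), seed = 1)
    got <- voronoi_bound_density(mos$points, r)
    expect_lt(abs(got$density - d) / d, 0.005)
    expect_equal(nnd_mean(mos$points, r), s, tolerance = 0.005)
    expect_equal(icd_mean(mos$points, r), s, tolerance = 0.005)
  }
})

test_that("NND matches hand enumeration on collinear points", {
  # x = 0, 1, 3: nearest distances 1, 1, 2
  pts <- cbind(c(0, 1, 3), c(0, 0, 0))
  expect_equal(nnd_mean(pts, roi(c(-1, -1), c(5, 2))), 4 / 3)
})

test_that("metrics equal the brute-force half-plane oracle on random sets", {
  r <- roi(c(20, 20), c(60, 60))
  set.seed(71)
  for (rep in 1:20) {
    n <- sample(10:40, 1)
    xy <- cbind(runif(n, 0, 100), runif(n, 0, 100))
    orc <- oracle_metrics(xy, r)
    if (!any(orc$bound)) next
    tess <- conemosaic:::tessellate(xy)
    bc <- conemosaic:::bound_cells(tess, r)
    expect_identical(which(bc$bound), which(orc$bound))
    expect_equal(bc$area[bc$bound], orc$areas[orc$bound], tolerance = 1e-9)
    got <- voronoi_bound_density(xy, r)
    expect_equal(got$density, orc$density, tolerance = 1e-9)
    expect_equal(nnd_mean(xy, r), orc$nnd_mean, tolerance = 1e-12)
    expect_equal(icd_mean(xy, r), orc$icd_mean, tolerance = 1e-9)
  }
})

test_that("KD-free nearest-neighbor search matches exhaustive search", {
  set.seed(5)
  xy <- cbind(runif(500, 0, 200), runif(500, 0, 200))
  r <- roi(c(0, 0), c(200, 200))
  brute <- mean(vapply(seq_len(500), function(i) {
    min(sqrt((xy[-i, 1] - xy[i, 1])^2 + (xy[-i, 2] - xy[i, 2])^2))
  }, numeric(1)))
  expect_equal(nnd_mean(xy, r), brute, tolerance = 1e-12)
})

test_that("density/spacing conversions are exact inverses", {
  expect_equal(density_to_spacing(11547), 10, tolerance = 1e-4)
  expect_equal(density_to_spacing(15528), 8.62, tolerance = 1e-3)
  for (d in c(500, 6741, 12375, 18798, 2e5)) {
    expect_equal(spacing_to_density(density_to_spacing(d)), d,
                 tolerance = 1e-12)
  }
  expect_error(density_to_spacing(0), "positive")
  expect_error(spacing_to_density(-1), "positive")
})

test_that("undefined-metric inputs raise errors", {
  r <- roi(c(0, 0), c(10, 10))
  expect_error(voronoi_bound_density(cbind(1, 1), r), "undefined metric")
  expect_error(nnd_mean(cbind(1, 1), r), "undefined metric")
  # all points collinear: tessellation is degenerate
  pts <- cbind(1:5, 1:5)
  expect_error(icd_mean(pts, roi(c(0, 0), c(10, 10))), "degenerate|undefined")
  # points far outside the ROI only
  far <- cbind(runif(10, 50, 60), runif(10, 50, 60))
  expect_error(voronoi_bound_density(far, r), "undefined metric")
})

test_that("metrics are invariant to rigid motion and equivariant to scaling", {
  set.seed(31)
  xy <- cbind(runif(120, 0, 120), runif(120, 0, 120))
  r <- roi(c(20, 20), c(80, 80))
  base <- mosaic_metrics(xy, r)

  # translation
  sh <- c(37.5, -12.25)
  r2 <- roi(r$origin + sh, r$size)
  m2 <- mosaic_metrics(cbind(xy[, 1] + sh[1], xy[, 2] + sh[2]), r2)
  expect_equal(m2$bound_density, base$bound_density, tolerance = 1e-9)
  expect_equal(m2$nnd_mean, base$nnd_mean, tolerance = 1e-9)
  expect_equal(m2$icd_mean, base$icd_mean, tolerance = 1e-9)

  # quarter-turn about the ROI center (the square ROI maps onto itself)
  ctr <- r$origin + r$size / 2
  rot <- cbind(ctr[1] - (xy[, 2] - ctr[2]), ctr[2] + (xy[, 1] - ctr[1]))
  m3 <- mosaic_metrics(rot, r)
  expect_equal(m3$bound_density, base$bound_density, tolerance = 1e-9)
  expect_equal(m3$nnd_mean, base$nnd_mean, tolerance = 1e-9)
  expect_equal(m3$icd_mean, base$icd_mean, tolerance = 1e-9)

  # scaling by k: distances scale by k, density by 1/k^2
  k <- 2.5
  r4 <- roi(r$origin * k, r$size * k)
  m4 <- mosaic_metrics(xy * k, r4)
  expect_equal(m4$nnd_mean, k * base$nnd_mean, tolerance = 1e-8)
  expect_equal(m4$icd_mean, k * base$icd_mean, tolerance = 1e-8)
  expect_equal(m4$bound_density, base$bound_density / k^2, tolerance = 1e-8)
})

test_that("random dropout does not raise bound density above the lattice value", {
  r <- roi(c(40, 40), c(160, 160))
  d <- 12000
  dens <- vapply(1:8, function(seed) {
    mos <- generate_mosaic(d, c(240, 240), dropout_frac = 0.25, seed = seed)
    voronoi_bound_density(mos$points, r)$density
  }, numeric(1))
  expect_lt(mean(dens), d)
})

test_that("ROI co-localization maps centers through the transform", {
  r <- roi(c(100, 200), c(200, 200), eccentricity_deg = 6, meridian = "superior")

  ident <- roi_transform(cbind(diag(2), c(0, 0)))
  expect_equal(colocalize_roi(r, ident), r)

  tr <- roi_transform(cbind(diag(2), c(50, -30)))
  r2 <- colocalize_roi(r, tr)
  expect_equal(r2$origin, r$origin + c(50, -30))
  expect_equal(r2$size, r$size)

  # a 0.3% inter-modality scale mismatch displaces the center by no more
  # than 0.3% of its norm
  sc <- roi_transform(suppressWarnings(cbind(1.003 * diag(2), c(0, 0))))
  r3 <- colocalize_roi(r, sc)
  ctr <- r$origin + r$size / 2
  ctr3 <- r3$origin + r3$size / 2
  expect_lte(sqrt(sum((ctr3 - ctr)^2)), 0.003 * sqrt(sum(ctr^2)) + 1e-12)

  expect_error(roi_transform(cbind(matrix(0, 2, 2), c(1, 1))), "invertible")
  expect_warning(roi_transform(cbind(2 * diag(2), c(0, 0))), "near-rigid")
})

test_that("NND never exceeds ICD on jittered mosaics", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(25L:60L, 1)
    xy <- cbind(runif(n, 0, 60), runif(n, 0, 60))
    r <- roi(c(10, 10), c(40, 40))
    ok <- tryCatch({
      m <- mosaic_metrics(xy, r)
      expect_lte(m$nnd_mean, m$icd_mean + 1e-12)
      TRUE
    }, error = function(e) grepl("undefined metric", conditionMessage(e)))
    expect_true(ok)
  }
})
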