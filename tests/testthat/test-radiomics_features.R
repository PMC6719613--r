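# The 3x3x1 worked example: rows (1 2 2 / 1 1 2 / 3 3 3) partitions into
# three zones of size 3 under 26-connectivity.
worked_example <- function() {
  lev <- array(0L, dim = c(3, 3, 1))
  lev[, , 1] <- matrix(c(1, 2, 2,
                         1, 1, 2,
                         3, 3, 3), nrow = 3, byrow = TRUE)
  make_disc(lev, 3)
}

test_that("zone labeling matches hand enumeration and the union-find oracle", {
  d <- worked_example()
  z <- label_zones(d, 26)
  got <- z[order(z[, "level"]), , drop = FALSE]
  expect_equal(unname(got), cbind(1:3, c(3, 3, 3)))

  # uniform ROI: one zone covering everything
  u <- make_disc(array(1L, dim = c(3, 4, 2)), 1)
  expect_equal(unname(label_zones(u, 26)), cbind(1L, 24L))
  expect_equal(unname(label_zones(u, 6)), cbind(1L, 24L))

  for (seed in 1:12) {
    d <- random_disc(4, 3, seed)
    for (conn in c(6, 26)) {
      z <- label_zones(d, conn)
      o <- oracle_zones(d$levels, conn)
      key <- function(lv, sz) sort(paste(lv, sz))
      expect_equal(key(z[, "level"], z[, "size"]), key(o$level, o$size))
    }
    # merging diagonal neighbors can only reduce the zone count
    expect_lte(nrow(label_zones(d, 26)), nrow(label_zones(d, 6)))
  }
})

test_that("GLSZM tabulation and conservation laws hold", {
  d <- worked_example()
  m <- build_glszm(d, 26)
  expect_equal(m$n_zones, 3)
  expect_equal(m$counts[1, 3], 1)
  expect_equal(m$counts[2, 3], 1)
  expect_equal(m$counts[3, 3], 1)
  expect_equal(sum(m$counts), m$n_zones)

  for (seed in 1:8) {
    d <- random_disc(5, 4, seed)
    m <- build_glszm(d, 26)
    i <- row(m$counts); j <- col(m$counts)
    expect_equal(sum(j * m$counts), sum(d$levels > 0))  # voxel conservation
    expect_equal(sum(m$counts), m$n_zones)
  }

  # uniform ROI of N voxels: a single maximal zone
  u <- make_disc(array(1L, dim = c(2, 3, 2)), 1)
  mu <- build_glszm(u, 26)
  expect_equal(mu$counts[1, 12], 1)
  expect_equal(sum(mu$counts), 1)
})

test_that("SZE/SZLGE/HGRE closed forms and oracle equivalence", {
  # parity checkerboard: face neighbors always differ, so every voxel is
  # its own zone under 6-connectivity and all zones are singletons -> SZE = 1
  chk <- array(0L, dim = c(2, 2, 2))
  for (z in 1:2) for (y in 1:2) for (x in 1:2)
    chk[x, y, z] <- 1L + (x + y + z) %% 2L
  d <- make_disc(chk, 2)
  m6 <- build_glszm(d, 6)
  expect_equal(sze(m6), 1)

  # single zone of size N -> SZE = 1/N^2
  u <- make_disc(array(1L, dim = c(3, 3, 3)), 1)
  expect_equal(sze(build_glszm(u, 26)), 1 / 27^2)

  # worked example: three zones of size 3
  m <- build_glszm(worked_example(), 26)
  expect_equal(sze(m), 1 / 9)
  expect_equal(szlge(m), 49 / 972)

  # szlge closed forms on crafted matrices
  m1 <- structure(list(counts = matrix(c(0, 0, 0, 0, 0, 1), 2, 3),
                       n_zones = 1, n_voxels = 3), class = "glszm")
  expect_equal(szlge(m1), 1 / 36)  # single zone, level 2, size 3

  # hgre closed forms
  r1 <- structure(list(counts = matrix(c(0, 0, 0, 0, 0, 1), 3, 2),
                       n_runs = 1, n_voxels = 2), class = "glrlm")
  expect_equal(hgre(r1), 9)  # single run at level 3

  for (seed in 1:10) {
    d <- random_disc(4, 3, seed)
    m <- build_glszm(d, 26)
    r <- build_glrlm(d)
    expect_equal(sze(m), oracle_sze(m$counts), tolerance = 1e-12)
    expect_equal(szlge(m), oracle_szlge(m$counts), tolerance = 1e-12)
    expect_equal(hgre(r), oracle_hgre(r$counts), tolerance = 1e-12)
  }
})

test_that("splitting a zone into smaller zones raises small-zone emphasis", {
  # one 1x1x8 bar: single zone vs split into two levels
  whole <- make_disc(array(1L, dim = c(1, 1, 8)), 2)
  split <- make_disc(array(c(rep(1L, 4), rep(2L, 4)), dim = c(1, 1, 8)), 2)
  expect_gt(sze(build_glszm(split, 26)), sze(build_glszm(whole, 26)))
})

test_that("GLRLM matches hand enumeration and the line-scan oracle", {
  # uniform 1x1xN bar
  u <- make_disc(array(1L, dim = c(1, 1, 5)), 1)
  r <- build_glrlm(u)
  expect_equal(r$counts[1, 5], 1)      # the long axis run
  expect_equal(r$counts[1, 1], 12 * 5) # every other direction: singletons
  expect_equal(r$n_runs, 12 * 5 + 1)

  # all-distinct levels: every run is a singleton over all 13 directions
  d <- make_disc(array(1:27, dim = c(3, 3, 3)), 27)
  r <- build_glrlm(d)
  expect_equal(ncol(r$counts), 1)
  expect_equal(r$n_runs, 13 * 27)

  for (seed in 1:8) {
    d <- random_disc(4, 3, seed)
    per_dir <- oracle_glrlm_per_direction(d$levels, d$n_levels)
    nv <- sum(d$levels > 0)
    for (m in per_dir) {
      j <- col(m)
      expect_equal(sum(j * m), nv)  # per-direction voxel conservation
    }
    agg <- Reduce(`+`, per_dir)
    got <- build_glrlm(d)$counts
    expect_equal(unname(got), agg[, seq_len(ncol(got)), drop = FALSE])
  }
})

test_that("first-order features match hand computations", {
  f <- first_order_features(c(1, 2, 3, 4))
  expect_equal(f[["FO_mean"]], 2.5)
  expect_equal(f[["FO_variance"]], 1.25)  # population variance
  expect_equal(f[["FO_median"]], 2.5)

  fc <- first_order_features(rep(3.7, 10))
  expect_equal(fc[["FO_variance"]], 0)
  expect_equal(fc[["FO_uniformity"]], 1)
  expect_equal(fc[["FO_entropy"]], 0)
  expect_true(is.na(fc[["FO_skewness"]]))

  set.seed(5)
  x <- rnorm(50)
  f <- first_order_features(x)
  expect_lte(f[["FO_min"]], f[["FO_median"]])
  expect_lte(f[["FO_median"]], f[["FO_max"]])
  expect_equal(f[["FO_energy"]], sum(x^2))
})

test_that("shape features have the right geometry", {
  m1 <- array(0, dim = c(3, 3, 3)); m1[2, 2, 2] <- 1
  s <- shape_features(roi_mask(m1), c(1, 1, 1))
  expect_equal(s[["SHAPE_volume_mm3"]], 1)
  expect_equal(s[["SHAPE_surface_mm2"]], 6)
  expect_equal(s[["SHAPE_max_diameter_mm"]], 0)

  cube <- array(0, dim = c(4, 4, 4)); cube[2:3, 2:3, 2:3] <- 1
  s <- shape_features(roi_mask(cube), c(1, 1, 1))
  expect_equal(s[["SHAPE_volume_mm3"]], 8)
  expect_equal(s[["SHAPE_surface_mm2"]], 24)
  expect_equal(s[["SHAPE_max_diameter_mm"]], sqrt(3), tolerance = 1e-12)

  # a ball is more spherical than an equal-volume thin slab
  ball <- array(0, dim = c(13, 13, 13))
  ctr <- 7
  for (z in 1:13) for (y in 1:13) for (x in 1:13)
    if ((x - ctr)^2 + (y - ctr)^2 + (z - ctr)^2 <= 25) ball[x, y, z] <- 1
  nb <- sum(ball)
  slab <- array(0, dim = c(25, 25, 3))
  slab[, , 2][seq_len(nb)] <- 1
  s_ball <- shape_features(roi_mask(ball), c(1, 1, 1))
  s_slab <- shape_features(roi_mask(slab), c(1, 1, 1))
  expect_gt(s_ball[["SHAPE_sphericity"]], s_slab[["SHAPE_sphericity"]])
})

test_that("extract_all emits a deterministic, complete variant row", {
  set.seed(23)
  vol1 <- generate_tumor_image(2, size = 16, seed = 9)
  vol2 <- generate_tumor_image(4, size = 16, seed = 10)
  banks <- list(ADC = decompose(vol1$volume), T2 = decompose(vol2$volume))
  msk <- vol1$mask
  schemes <- default_scheme_grid(c(8, 16))
  row <- extract_all(banks, msk, schemes = schemes)

  # bookkeeping: 2 seq x (4 shape + 9 x 12 first-order + 9 x 2 x 28 texture)
  expect_length(row, 2 * (4 + 9 * 12 + 9 * 2 * 28))
  expect_identical(names(row), sort(names(row)))

  # determinism
  row2 <- extract_all(banks, msk, schemes = schemes)
  expect_identical(row, row2)

  # scheme order invariance (values identical under re-sorted keys)
  row3 <- extract_all(banks, msk, schemes = rev(schemes))
  expect_identical(row, row3[names(row)])

  # variant keys factor into base features
  expect_equal(variant_base("ADC|LLL|FBN32|GLSZM_SZE"), "ADC|GLSZM_SZE")
})
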