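# Alignment, stain segmentation and islet object construction.

make_raster <- function(m, px = 1, origin = c(0, 0)) {
  attr(m, "pixel_size") <- px
  attr(m, "origin") <- origin
  m
}

test_that("stain segmentation applies the 50 um^2 region floor exactly", {
  m <- matrix(0, 60, 60)
  m[10:17, 10:14] <- 1       # 8 x 5 px = 40 um^2 at 1 um/px
  r <- segment_stain_regions(make_raster(m), 0.5)
  expect_length(r, 0L)
  m2 <- matrix(0, 60, 60)
  m2[10:19, 10:15] <- 1      # 10 x 6 px = 60 um^2
  r2 <- segment_stain_regions(make_raster(m2), 0.5)
  expect_length(r2, 1L)
  expect_equal(region_area(r2[[1]]), 60, tolerance = 1e-9)
  expect_length(segment_stain_regions(make_raster(matrix(0, 20, 20)), 0.5), 0L)
  expect_error(segment_stain_regions(make_raster(m2), 99), "threshold")
})

test_that("segmented pixel polygons sit at the correct coordinates", {
  m <- matrix(0, 40, 40)
  m[11:20, 21:30] <- 1       # rows 11-20 (y), cols 21-30 (x)
  r <- segment_stain_regions(make_raster(m, px = 0.5, origin = c(100, 200)),
                             0.5, min_area = 10)
  bb <- region_bbox(r[[1]])
  expect_equal(bb, c(100 + 20 * 0.5, 200 + 10 * 0.5,
                     100 + 30 * 0.5, 200 + 20 * 0.5), tolerance = 1e-9)
  expect_equal(region_area(r[[1]]), 100 * 0.25, tolerance = 1e-9)
})

test_that("rasterization round-trips polygon area at fine pixel sizes", {
  p <- disc_poly(100, 100, 40, 128)
  m <- rasterize_region(p, c(0, 0, 200, 200), 0.25)
  expect_equal(sum(m > 0) * 0.25^2, region_area(p),
               tolerance = 0.01 * region_area(p))
})

test_that("islet construction merges, fills, and filters by size and border", {
  tissue <- tissue_section("t", tissue = rect_poly(0, 0, 2000, 2000))
  # two touching stain blocks merge into one 1200 um^2 islet
  st <- list(A = rect_poly(500, 500, 530, 520),
             B = rect_poly(530, 500, 560, 520))
  isl <- build_islet_objects(st, tissue)
  expect_length(isl$polygons, 1L)
  expect_equal(isl$table$area, 1200, tolerance = 1e-6)
  # a filled 900 um^2 component is removed
  small <- list(A = rect_poly(1000, 1000, 1030, 1030))   # 900 um^2
  expect_length(build_islet_objects(small, tissue)$polygons, 0L)
  # interior holes are filled before the size filter
  ringst <- list(A = poly_op(rect_poly(200, 200, 236, 236),
                             rect_poly(210, 210, 226, 226), "minus"))
  # stained area 1040 um^2; filled area 1296 um^2
  ri <- build_islet_objects(ringst, tissue)
  expect_equal(ri$table$area, 36^2, tolerance = 1e-6)
  # an object 5 um from the tissue border is removed
  near <- list(A = rect_poly(5, 500, 45, 530))
  expect_length(build_islet_objects(near, tissue)$polygons, 0L)
  nearok <- list(A = rect_poly(15, 500, 55, 530))
  expect_length(build_islet_objects(nearok, tissue)$polygons, 1L)
  expect_error(build_islet_objects(list(), tissue), "empty stain set")
})

test_that("islet construction is idempotent on built polygons", {
  sy <- suppressWarnings(synth_section("Ctrl", "PT", seed = 12,
                                       width_mm = 3, height_mm = 3))
  det <- build_islet_objects(sy$stains[c("CHGA", "ProINS", "INS",
                                         "GCG", "SST", "PPY")], sy$section)
  again <- build_islet_objects(list(islets = det$polygons), sy$section)
  expect_identical(length(again$polygons), length(det$polygons))
  a1 <- sort(vapply(det$polygons, region_area, numeric(1)))
  a2 <- sort(vapply(again$polygons, region_area, numeric(1)))
  expect_equal(a2, a1, tolerance = 1e-9)
})

test_that("planted islets are recovered one-to-one from stain geometry", {
  sy <- suppressWarnings(synth_section("T1DS", "PH", seed = 13,
                                       width_mm = 5, height_mm = 5))
  det <- build_islet_objects(sy$stains[c("CHGA", "ProINS", "INS",
                                         "GCG", "SST", "PPY")], sy$section)
  m <- match_islets_to_truth(det, sy)
  big <- sy$truth$area[m$truth_id] >= 1200
  expect_gte(mean(m$iou[big] >= 0.95), 0.99)
  expect_identical(length(det$polygons), nrow(sy$truth))
  # a planted sub-1000 um^2 endocrine cluster never appears
  st <- sy$stains[c("CHGA", "ProINS", "INS", "GCG", "SST", "PPY")]
  st$CHGA <- c(st$CHGA, list(rect_poly(100, 100, 128, 128)))  # 784 um^2
  det2 <- build_islet_objects(st, sy$section)
  expect_identical(length(det2$polygons), length(det$polygons))
})

test_that("affine estimation recovers planted transforms at 5 um working resolution", {
  sy <- suppressWarnings(synth_section("Ctrl", "PT", seed = 21,
                                       width_mm = 2.5, height_mm = 2.5,
                                       n_islets = 14))
  base <- rasterize_region(sy$islets, c(0, 0, 2500, 2500), 2)
  # identity: moving == base
  f0 <- estimate_affine(base, base, working_resolution = 5)
  expect_lt(max(abs(f0$transform - affine_transform())), 1e-6)
  # planted shift (100, -50) um with a 2 degree rotation
  planted <- affine_transform(tx = 100, ty = -50, theta = 2 * pi / 180,
                              centre = c(1250, 1250))
  moving <- rasterize_region(apply_affine(planted, sy$islets),
                             c(0, 0, 2500, 2500), 2)
  fit <- estimate_affine(moving, base, working_resolution = 5)
  # estimate maps moving -> base; composed with the planted transform it
  # should be the identity at landmark positions
  comp <- compose_affine(fit$transform, planted)
  lm <- cbind(sy$truth$x, sy$truth$y)
  err <- sqrt(rowSums((apply_affine(comp, lm[, 1], lm[, 2]) - lm)^2))
  expect_lte(max(err), 5)
  # planted isotropic scale recovered within 0.002
  sc <- affine_transform(sx = 1.02, sy = 1.02, centre = c(1250, 1250))
  moving_s <- rasterize_region(apply_affine(sc, sy$islets),
                               c(0, 0, 2500, 2500), 2)
  fit_s <- estimate_affine(moving_s, base, working_resolution = 5)
  expect_lt(abs(fit_s$params$sx * fit_s$params$sy - 1 / 1.02^2), 2 * 0.002)
  expect_error(estimate_affine(matrix(0, 5, 5), base, pixel_size = 2),
               "empty raster")
})

test_that("affine utilities compose and invert consistently", {
  A <- affine_transform(tx = 3, ty = -2, theta = 0.3, sx = 1.1, sy = 0.9,
                        shear = 0.05, centre = c(10, 20))
  I2 <- compose_affine(A, invert_affine(A))
  expect_equal(I2, affine_transform(), tolerance = 1e-10)
  expect_error(invert_affine(cbind(matrix(0, 2, 2), c(1, 1))),
               "not invertible")
})

test_that("stain unmixing inverts the Beer-Lambert forward model", {
  V <- cbind(c(0.65, 0.70, 0.29), c(0.07, 0.99, 0.11))  # stain OD vectors
  V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
  # white pixel: zero density everywhere
  expect_equal(as.numeric(unmix_stains(matrix(c(255, 255, 255), 1), V)),
               c(0, 0), tolerance = 1e-9)
  # pure chromogen A at density 0.8: channel A recovered, channel B zero
  I_a <- 255 * 10^(-0.8 * V[, 1])
  d <- unmix_stains(matrix(I_a, 1), V)
  expect_equal(as.numeric(d), c(0.8, 0), tolerance = 1e-6)
  # synthetic two-stain composite: per-pixel recovery within 0.02 OD RMSE
  set.seed(1)
  D <- cbind(runif(500, 0, 1.2), runif(500, 0, 0.8))
  I <- 255 * 10^(-(D %*% t(V)))
  Dhat <- unmix_stains(I, V)
  expect_lt(sqrt(mean((Dhat - D)^2)), 0.02)
  expect_error(unmix_stains(matrix(255, 1, 3), cbind(V[, 1], V[, 1])),
               "rank deficient")
})
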