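# Hormone area measurement, overlap statistics, deficiency phenotypes,
# section summaries and size-binned curves.

test_that("hormone areas are exact polygon intersections", {
  islet <- rect_poly(0, 0, 100, 100)
  stains <- list(GCG = rect_poly(0, 0, 100, 30),     # 30% of islet
                 ProINS = rect_poly(-50, -50, 150, 150),  # superset
                 SST = rect_poly(500, 500, 520, 520))     # disjoint
  hp <- measure_hormone_areas(islet, stains)
  expect_equal(hp$row$frac_GCG, 0.30, tolerance = 1e-9)
  expect_equal(hp$row$frac_ProINS, 1, tolerance = 1e-9)
  expect_equal(hp$row$area_SST, 0)
  expect_equal(hp$row$area_CHGA, 0)   # unsupplied hormone measured as zero
  expect_equal(hp$row$endocrine_union_area, 1e4, tolerance = 1e-6)
  expect_error(
    measure_hormone_areas(islet, list(ProINS = rect_poly(0, 0, 10, 10),
                                      ProINS_hi = rect_poly(0, 0, 50, 50))),
    "ProINS_hi")
})

test_that("planted per-islet fractions are recovered through the vector path", {
  sy <- suppressWarnings(synth_section("AAb", "PT", seed = 14,
                                       width_mm = 4, height_mm = 4))
  det <- build_islet_objects(sy$stains[c("CHGA", "ProINS", "INS",
                                         "GCG", "SST", "PPY")], sy$section)
  m <- match_islets_to_truth(det, sy)
  for (i in seq_along(det$polygons)) {
    st <- lapply(sy$stains, `[[`, m$truth_id[i])
    names(st)[names(st) == "ProINS_hi"] <- "ProINS_hi"
    hp <- measure_hormone_areas(det$polygons[[i]], st, pairwise = FALSE)
    tr <- sy$truth[m$truth_id[i], ]
    expect_equal(hp$row$frac_ProINS, tr$proins, tolerance = 1e-6)
    expect_equal(hp$row$frac_GCG, tr$gcg, tolerance = 1e-6)
    expect_equal(hp$row$proins_hi_frac, tr$proins_hi, tolerance = 1e-6)
  }
})

test_that("fractions survive a raster round-trip at 0.25 um within 0.01", {
  sy <- suppressWarnings(synth_section("Ctrl", "PH", seed = 15,
                                       width_mm = 1.2, height_mm = 1.2,
                                       n_islets = 4))
  worst <- 0
  for (i in seq_along(sy$islets)) {
    bb <- region_bbox(sy$islets[[i]]) + c(-20, -20, 20, 20)
    for (h in c("ProINS", "GCG", "PPY", "CHGA")) {
      m <- rasterize_region(sy$stains[[h]][[i]], bb, 0.25)
      segs <- segment_stain_regions(m, 0.5, min_area = 10)
      a <- if (length(segs)) sum(vapply(segs, region_area, numeric(1))) else 0
      fr <- a / sy$truth$area[i]
      key <- c(ProINS = "proins", GCG = "gcg", PPY = "ppy", CHGA = "chga")[[h]]
      worst <- max(worst, abs(fr - sy$truth[[key]][i]))
    }
  }
  expect_lte(worst, 0.01)
})

test_that("Jaccard indices satisfy the overlap axioms", {
  islet <- rect_poly(0, 0, 100, 100)
  stains <- list(CHGA = rect_poly(0, 0, 100, 100),
                 ProINS = rect_poly(0, 0, 100, 100),     # identical to CHGA
                 GCG = rect_poly(0, 0, 50, 20),          # 1000 um^2
                 INS = rect_poly(25, 0, 75, 20),         # 1000, overlap 500
                 SST = rect_poly(90, 90, 99, 99))
  J <- jaccard_matrix(measure_hormone_areas(islet, stains))
  expect_equal(J["CHGA", "ProINS"], 1, tolerance = 1e-9)
  expect_equal(J["GCG", "INS"], 500 / 1500, tolerance = 1e-9)
  expect_equal(J["GCG", "SST"], 0)
  expect_true(isSymmetric(J))
  expect_true(all(diag(J)[c("CHGA", "ProINS", "GCG", "INS", "SST")] == 1))
  expect_true(is.na(J["IAPP", "IAPP"]))     # absent stain: undefined
  expect_true(all(J[!is.na(J)] >= 0 & J[!is.na(J)] <= 1))
  bad <- measure_hormone_areas(islet, stains)$pairs
  bad$intersection[1] <- -5
  expect_error(jaccard_matrix(bad), "negative")
})

test_that("the 1% boundary is strict for deficiency, inclusive for positivity", {
  prof <- data.frame(islet_id = 1:3)
  for (h in HORMONES) prof[[paste0("frac_", h)]] <- c(0.005, 0.01, 0)
  out <- classify_deficiency(prof)
  expect_identical(out$idi, c(TRUE, FALSE, TRUE))        # 0.005 -> IDI
  expect_identical(out$ppy_pos, c(FALSE, TRUE, FALSE))   # exactly 1% positive
  expect_true(all(unlist(out[3, paste0("deficient_", HORMONES)])))
  expect_identical(out$idi_ins, out$idi_proins)          # both emitted
  alt <- classify_deficiency(prof, idi_definition = "INS")
  expect_identical(alt$idi, alt$idi_ins)
})

test_that("section summaries scale fractions into masses", {
  sec <- tissue_section("s", tissue = rect_poly(0, 0, 10000, 10000)) # 100 mm^2
  prof <- data.frame(islet_id = 1, islet_area = 1e6)
  for (h in HORMONES) prof[[paste0("area_", h)]] <- 0
  prof$area_INS <- 1e6   # 1% of parenchyma
  s <- section_summary(sec, prof, regional_weight_g = 30)
  expect_equal(s$fraction_INS, 0.01)
  expect_equal(s$mass_INS_g, 0.3)
  expect_equal(s$islet_density_mm2, 0.01)
  expect_equal(s$islet_area_fraction, 0.01)
  # missing weight: masses NA, fractions intact
  expect_warning(s2 <- section_summary(sec, prof), "weight")
  expect_true(is.na(s2$mass_INS_g))
  expect_equal(s2$fraction_INS, 0.01)
  # zero islets
  s0 <- section_summary(sec, prof[0, ], regional_weight_g = 30)
  expect_equal(s0$n_islets, 0)
  expect_equal(s0$islet_density_mm2, 0)
  expect_equal(s0$fraction_INS, 0)
})

test_that("cumulative section fractions match generator truth", {
  sy <- suppressWarnings(synth_section("T1DS", "PT", seed = 16,
                                       width_mm = 4, height_mm = 4))
  det <- build_islet_objects(sy$stains[c("CHGA", "ProINS", "INS",
                                         "GCG", "SST", "PPY")], sy$section)
  res <- analyze_section(sy$section, sy$stains, sy$points[, c("x", "y", "kind")],
                         pairwise = FALSE)
  m <- match_islets_to_truth(res$islets, sy)
  tr <- sy$truth[m$truth_id, ]
  par_area <- region_area(sy$section$parenchyma)
  expect_equal(res$summary$fraction_GCG,
               sum(tr$gcg * tr$area) / par_area, tolerance = 0.01)
  expect_equal(res$summary$islet_area_fraction,
               sum(tr$area) / par_area, tolerance = 0.01)
})

test_that("per-islet sums equal one-pass section-level intersections", {
  islets <- list(rect_poly(0, 0, 100, 100), rect_poly(200, 0, 300, 100))
  stain <- list(GCG = rect_poly(50, 0, 250, 100))  # spans both islets
  per_islet <- sum(vapply(islets, function(p)
    region_area(poly_op(stain$GCG, p, "intersection")), numeric(1)))
  one_pass <- region_area(poly_op(stain$GCG, poly_union_all(islets),
                                  "intersection"))
  expect_equal(per_islet, one_pass, tolerance = 1e-6 * one_pass)
})

test_that("raising a threshold never increases the segmented stain area", {
  set.seed(2)
  m <- matrix(runif(100 * 100), 100, 100)
  attr(m, "pixel_size") <- 1; attr(m, "origin") <- c(0, 0)
  areas <- vapply(c(0.2, 0.4, 0.6, 0.8), function(th) {
    r <- segment_stain_regions(m, th, min_area = 0)
    if (length(r)) sum(vapply(r, region_area, numeric(1))) else 0
  }, numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("size-binned curves recover a planted one-phase association", {
  set.seed(8)
  areas <- exp(runif(2000, log(1000), log(1e5)))
  truthf <- function(a) 0.6 + 0.3 * exp(-1e-4 * a)
  vals <- truthf(areas) + rnorm(2000, 0, 0.02)
  sc <- size_binned_curves(areas, vals)
  expect_identical(nrow(sc$bins), 14L)
  expect_equal(sc$fit$plateau, 0.6, tolerance = 0.1)
  expect_equal(sc$fit$span, 0.3, tolerance = 0.1)
  expect_equal(sc$fit$k, 1e-4, tolerance = 0.1)
  expect_gt(sc$fit$r_squared, 0.75)
  # a bin holding fewer than 3 islets is reported missing
  a2 <- c(rep(1000, 10) * exp(runif(10, 0, 0.1)), 5e4, 1e5, 1.0001e5)
  sc2 <- size_binned_curves(a2, seq_along(a2) * 1.0)
  counts <- sc2$bins$n
  expect_true(any(counts < 3))
  expect_true(all(is.na(sc2$bins$mean[counts < 3])))
  expect_true(all(!is.na(sc2$bins$mean[counts >= 3])))
  # constant property: no usable fit, handled gracefully
  sc3 <- size_binned_curves(areas[1:100], rep(0.5, 100))
  expect_null(sc3$fit)
  expect_error(size_binned_curves(c(1000, 2000), c(1, 2)), "at least 3")
})
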