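test_that("islet areas reproduce the calibrated size structure", {
  a <- donor_archetype("Ctrl", "PT")
  x <- sample_islet_areas(a, 10000, seed = 1)
  expect_true(all(x >= 1000))
  # ~82% of islets in the 10^3-10^4 um^2 range, ~50% below 3000 um^2
  expect_equal(mean(x < 1e4), 0.82, tolerance = 0.02)
  expect_equal(mean(x < 3000), 0.50, tolerance = 0.03)
})

test_that("area sampling is seeded and handles degenerate spread", {
  a <- donor_archetype("AAb", "PH")
  expect_identical(sample_islet_areas(a, 1, seed = 7),
                   sample_islet_areas(a, 1, seed = 7))
  a0 <- donor_archetype("AAb", "PH", override = list(size_log_sd = 0))
  x <- sample_islet_areas(a0, 5, seed = 1)
  expect_true(all(x == max(1000, exp(a0$size_log_mean))))
  expect_error(sample_islet_areas(a, 0), "n must be")
})

test_that("archetype validation enforces the field invariants", {
  expect_error(donor_archetype("Ctrl", "PT",
                               override = list(idi_fraction = 1.4)),
               "fraction")
  expect_error(donor_archetype("Ctrl", "PT",
                               override = list(islet_density = -1)),
               "islet_density")
  expect_error(donor_archetype("Ctrl", "PT",
                               override = list(shape_noise = 0.9)),
               "shape_noise")
})

test_that("placement respects mode, target area, margins and overlap", {
  boundary <- rect_poly(0, 0, 8000, 8000)
  # single islet: exact target area
  p1 <- place_islets(boundary, 1000, mode = "CSR", seed = 1)
  expect_equal(region_area(p1[[1]]), 1000, tolerance = 1e-9)
  # half-region: all centroids in the left half
  ph <- place_islets(boundary, rep(2000, 40), mode = "half_region", seed = 2)
  cx <- vapply(ph, function(r) attr(r, "centre")[1], numeric(1))
  expect_true(all(cx <= 4000))
  # uncinate: lower-left sub-box
  pu <- place_islets(boundary, rep(2000, 20), mode = "uncinate", seed = 3)
  cu <- t(vapply(pu, function(r) attr(r, "centre"), numeric(2)))
  expect_true(all(cu[, 1] <= 0.40 * 8000) && all(cu[, 2] >= 0.55 * 8000))
  # non-overlap and border margin
  pp <- place_islets(boundary, rep(5000, 60), mode = "CSR", seed = 4)
  min_border <- min(vapply(pp, poly_boundary_distance, numeric(1), b = boundary))
  expect_gte(min_border, 10)
  max_overlap <- 0
  for (i in seq_along(pp)) for (j in seq_len(i - 1)) {
    max_overlap <- max(max_overlap,
                       region_area(poly_op(pp[[i]], pp[[j]], "intersection")))
  }
  expect_lt(max_overlap, 1e-9)
  # packing failure names the achieved count
  expect_error(place_islets(rect_poly(0, 0, 400, 400), rep(30000, 10),
                            seed = 5, max_tries = 20L),
               "placed [0-9]+ of 10")
})

test_that("composition draws honor deficiency branches and curves", {
  # clinical-stage archetype: beta territory pinned below the 1% boundary
  tl <- donor_archetype("T1DL", "PT")
  draws <- replicate(300, assign_composition(tl, 2500)$fractions[["proins"]])
  expect_gte(mean(draws < 0.01), 0.99)
  # forced GCG-deficient branch on a small islet: alpha < 1%, beta >= 1%
  ct <- donor_archetype("Ctrl", "PT",
                        override = list(gcg_deficient_small_fraction = 1,
                                        idi_fraction = 0,
                                        ppy_uncinate_fraction = 0))
  set.seed(3)
  cc <- assign_composition(ct, 1500)
  expect_identical(cc$label, "III")
  expect_lt(cc$fractions[["gcg"]], 0.01)
  expect_gte(cc$fractions[["proins"]], 0.01)
  # flat curves with no noise: territory fraction equals the plateau
  flat <- donor_archetype("Ctrl", "PT", override = list(
    idi_fraction = 0, gcg_deficient_small_fraction = 0,
    ppy_uncinate_fraction = 0, composition_noise_sd = 0,
    composition_curves = list(beta = list(plateau = 0.4, span = 0, k = 1e-4),
                              alpha = list(plateau = 0.4, span = 0, k = 1e-4),
                              delta = list(plateau = 0.1, span = 0, k = 1e-4),
                              gamma = list(plateau = 0.1, span = 0, k = 1e-4))))
  cf <- assign_composition(flat, 5000, seed = 1)
  expect_equal(unname(cf$territories["beta"]), 0.4, tolerance = 1e-12)
  expect_equal(sum(cf$territories), 1, tolerance = 1e-12)
  expect_error(assign_composition(tl, 500), "islet definition")
})

test_that("CD45 scattering follows the planted point-process law", {
  a <- donor_archetype("Ctrl", "PT")
  islet <- disc_poly(0, 0, 60, 64)
  # zero rates give zero points
  a0 <- donor_archetype("Ctrl", "PT", override = list(
    cd45_rates = list(baseline = list(intra = 0, peri = 0),
                      high_burden = list(intra = 0, peri = 0),
                      residual = list(intra = 0, peri = 0)),
    nuclei_density = 0))
  s0 <- scatter_cd45(islet, a0, seed = 1)
  expect_identical(s0$n_intra + s0$n_peri, 0L)
  expect_identical(nrow(s0$nuclei), 0L)
  # insulitic plants carry at least 15 associated cells
  si <- scatter_cd45(islet, a, seed = 2, insulitic = TRUE)
  expect_gte(si$n_intra + si$n_peri, 15)
  # Poisson mean: rate r over area A gives mean r*A/1000 across seeds
  r_intra <- 0.5
  ah <- donor_archetype("Ctrl", "PT", override = list(
    cd45_rates = list(baseline = list(intra = r_intra, peri = 0),
                      high_burden = list(intra = 0, peri = 0),
                      residual = list(intra = 0, peri = 0))))
  A <- region_area(islet)
  counts <- vapply(1:200, function(s)
    scatter_cd45(islet, ah, seed = s)$n_intra, numeric(1))
  mu <- r_intra * A / 1000
  se <- sqrt(mu / 200)
  expect_lt(abs(mean(counts) - mu), 3 * se)
  # nuclei always dominate CD45 in every compartment
  sh <- scatter_cd45(islet, a, seed = 3, burden = "high_burden")
  for (cmp in c("intra", "peri")) {
    expect_gte(sum(sh$nuclei$compartment == cmp),
               sum(sh$cd45$compartment == cmp))
  }
})

test_that("sections satisfy the geometric containment invariants", {
  sy <- suppressWarnings(synth_section("Ctrl", "PH", seed = 9,
                                       width_mm = 4, height_mm = 4))
  for (i in seq_along(sy$islets)) {
    # islet inside parenchyma (exact: clipping removes nothing)
    out <- poly_op(sy$islets[[i]], sy$section$parenchyma, "minus")
    expect_lt(region_area(out), 1e-6)
    for (h in names(sy$stains)) {
      leak <- poly_op(sy$stains[[h]][[i]], sy$islets[[i]], "minus")
      expect_lt(region_area(leak), 1e-6)
    }
  }
  # planted point counts match the truth table exactly
  cd <- sy$points[sy$points$kind == "cd45", ]
  tab <- table(factor(cd$islet_id, levels = seq_along(sy$islets)))
  expect_identical(as.integer(tab),
                   as.integer(sy$truth$cd45_intra + sy$truth$cd45_peri))
})

test_that("sections are byte-identical for identical seeds", {
  s1 <- suppressWarnings(synth_section("T1DS", "PT", seed = 4,
                                       width_mm = 3, height_mm = 3))
  s2 <- suppressWarnings(synth_section("T1DS", "PT", seed = 4,
                                       width_mm = 3, height_mm = 3))
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$points, s2$points)
  expect_identical(s1$islets, s2$islets)
})

test_that("insulin-deficiency increases monotonically across disease stages", {
  frac <- vapply(DONOR_GROUPS, function(g) {
    sy <- suppressWarnings(synth_section(g, "PT", seed = 31, n_islets = 300,
                                         width_mm = 16, height_mm = 16))
    mean(sy$truth$proins < 0.01)
  }, numeric(1))
  expect_true(all(diff(frac[c("Ctrl", "AAb", "T1DS", "T1DL")]) > 0))
})
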