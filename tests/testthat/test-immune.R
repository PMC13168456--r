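# Peri-islet regions, cell attribution and insulitis scoring.

test_that("an isolated islet's band is the closed-form annulus", {
  islet <- disc_poly(0, 0, 50, 256)
  pr <- build_peri_regions(list(islet))
  expect_equal(pr$table$area, pi * (70^2 - 50^2),
               tolerance = 0.005 * pi * (70^2 - 50^2))
})

test_that("bands of neighboring islets split along the equidistant locus", {
  # two circles 10 um apart: candidate bands overlap heavily
  a <- disc_poly(0, 0, 50, 128)
  b <- disc_poly(110, 0, 50, 128)
  pr <- build_peri_regions(list(a, b))
  overlap <- region_area(poly_op(pr$regions[[1]], pr$regions[[2]],
                                 "intersection"))
  expect_lt(overlap, 1e-6)
  # sampled band points lie nearer to their own islet
  for (k in 1:2) {
    own <- list(a, b)[[k]]; other <- list(a, b)[[3 - k]]
    for (rg in pr$regions[[k]]) {
      d_own <- dist_to_boundary(rg$x, rg$y, own)
      d_oth <- dist_to_boundary(rg$x, rg$y, other)
      expect_true(all(d_own <= d_oth + 2.5))  # boundary-sampling tolerance
    }
  }
  # by symmetry the two half-bands have equal area
  expect_equal(pr$table$area[1], pr$table$area[2], tolerance = 0.01)
  expect_error(build_peri_regions(list(a, disc_poly(10, 0, 50, 128))),
               "overlap")
})

test_that("bands are clipped to the tissue polygon", {
  sec <- tissue_section("t", tissue = rect_poly(0, 0, 1000, 1000))
  islet <- disc_poly(65, 500, 50, 128)  # 15 um from the tissue edge
  pr <- build_peri_regions(list(islet), sec)
  full <- pi * (70^2 - 50^2)
  expect_lt(pr$table$area, full - 100)
  bb <- region_bbox(pr$regions[[1]])
  expect_gte(bb[1], 0)
})

test_that("points are attributed by compartment with exact boundary rules", {
  sec <- tissue_section("t", tissue = rect_poly(-500, -500, 1500, 500))
  islets <- list(disc_poly(0, 0, 50, 256), disc_poly(1000, 0, 50, 256))
  pts <- data.frame(
    x = c(0,    50,   0,     0,   1000, -470),
    y = c(0,    0,    60,    75,  10,   -470),
    kind = "cd45")
  # centroid -> intra; on boundary -> intra; 10 um out -> peri;
  # 25 um out -> unassigned; second islet centroid -> islet 2;
  # far corner -> unassigned
  imm <- assign_cells(pts, pts, islets, section = sec)
  a <- imm$assignment$cd45
  expect_identical(a$compartment,
                   c("intra", "intra", "peri", "none", "intra", "none"))
  expect_identical(a$islet_id[c(1, 2, 3, 5)], c(1L, 1L, 1L, 2L))
  expect_identical(imm$profiles$intra_cd45, c(2L, 1L))
  expect_identical(imm$profiles$peri_cd45, c(1L, 0L))
  # partition: intra + peri + unassigned = total
  expect_identical(sum(imm$profiles$intra_cd45) + sum(imm$profiles$peri_cd45) +
                     sum(a$compartment == "none"), nrow(pts))
})

test_that("peri points go to the nearer islet, ties to the lower id", {
  islets <- list(disc_poly(0, 0, 50, 256), disc_poly(120, 0, 50, 256))
  pts <- data.frame(x = c(55, 65, 60), y = c(0, 0, 0), kind = "cd45")
  imm <- assign_cells(pts, pts, islets)
  a <- imm$assignment$cd45
  expect_identical(a$islet_id, c(1L, 2L, 1L))  # 60 is equidistant -> islet 1
  expect_true(all(a$compartment == "peri"))
})

test_that("planted synthetic counts are recovered exactly", {
  sy <- suppressWarnings(synth_section("T1DS", "PH", seed = 23,
                                       width_mm = 4, height_mm = 4))
  res <- analyze_section(sy$section, sy$stains, sy$points[, c("x", "y", "kind")],
                         pairwise = FALSE)
  m <- match_islets_to_truth(res$islets, sy)
  tr <- sy$truth[m$truth_id, ]
  expect_identical(res$immune$intra_cd45, as.integer(tr$cd45_intra))
  expect_identical(res$immune$peri_cd45, as.integer(tr$cd45_peri))
  # every band is disjoint from every other (numerical zero)
  pr <- res$peri$regions
  worst <- 0
  for (i in seq_along(pr)) for (j in seq_len(i - 1L)) {
    b1 <- region_bbox(pr[[i]]); b2 <- region_bbox(pr[[j]])
    if (b1[1] <= b2[3] && b1[3] >= b2[1] && b1[2] <= b2[4] && b1[4] >= b2[2])
      worst <- max(worst, region_area(poly_op(pr[[i]], pr[[j]], "intersection")))
  }
  expect_lt(worst, 1e-6)
})

test_that("adding a CD45 point never decreases counts or flags", {
  islets <- list(disc_poly(0, 0, 60, 128))
  set.seed(5)
  base_pts <- data.frame(x = runif(20, -55, 55), y = runif(20, -55, 55),
                         kind = "cd45")
  nuc <- base_pts
  p0 <- assign_cells(base_pts, nuc, islets)$profiles
  more <- rbind(base_pts, data.frame(x = 0, y = 0, kind = "cd45"))
  p1 <- assign_cells(more, nuc, islets)$profiles
  expect_gte(p1$intra_cd45, p0$intra_cd45)
  expect_gte(p1$peri_cd45, p0$peri_cd45)
  expect_gte(p1$intra_freq, p0$intra_freq)
  expect_gte(p1$total_associated, p0$total_associated)
  expect_true(p1$insulitic >= p0$insulitic)
})

test_that("the insulitis threshold is exact at 14 versus 15 cells", {
  prof <- data.frame(intra_cd45 = c(10, 7, 0), peri_cd45 = c(5, 7, 0))
  out <- flag_insulitis(prof)
  expect_identical(out$insulitic, c(TRUE, FALSE, FALSE))
  expect_identical(out$total_associated, c(15, 14, 0))
})

test_that("donor diagnosis requires three insulitic islets", {
  mk <- function(counts, donor = "d1", section = "s1")
    flag_insulitis(data.frame(donor_id = donor, section_id = section,
                              islet_id = seq_along(counts),
                              intra_cd45 = counts, peri_cd45 = 0))
  expect_true(diagnose_insulitis(mk(c(15, 15, 15, 0)))$insulitis)
  expect_false(diagnose_insulitis(mk(c(100, 100)))$insulitis)
  expect_false(diagnose_insulitis(mk(c(14, 14, 14)))$insulitis)
  # pooling across sections and regions is the default
  two <- rbind(mk(c(15, 15), section = "PT"), mk(15, section = "PH"))
  expect_true(diagnose_insulitis(two)$insulitis)
  expect_false(diagnose_insulitis(two, per_section = TRUE)$insulitis)
  # invariant to islet and section ordering
  shuf <- two[c(3, 1, 2), ]
  expect_identical(diagnose_insulitis(shuf)$insulitis,
                   diagnose_insulitis(two)$insulitis)
})

test_that("donor CD45 metrics cover the degenerate extremes", {
  mk <- function(cd45) data.frame(
    donor_id = "d", islet_id = seq_along(cd45),
    intra_cd45 = cd45, peri_cd45 = 0L,
    intra_nuclei = 10L, peri_nuclei = 10L,
    islet_area = 3000, peri_area = 5000,
    intra_freq = 100 * cd45 / 10, peri_freq = 0,
    total_associated = cd45, insulitic = cd45 >= 15)
  z <- cohort_cd45_metrics(mk(c(0, 0, 0)))
  expect_equal(z$frac_islets_ge1_cd45, 0)
  o <- cohort_cd45_metrics(mk(c(1, 2, 30)))
  expect_equal(o$frac_islets_ge1_cd45, 1)
  expect_equal(o$total_associated_cd45, 33)
  expect_equal(o$associated_cd45_density_mm2, 33 / (3 * 8000 / 1e6))
  expect_equal(o$n_insulitic, 1)
})
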