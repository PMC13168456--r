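# Shared fixtures. Expensive cohort simulations are built once per test
# session and cached in this environment.

.fixture_env <- new.env(parent = emptyenv())

# The demonstration cohort at generator defaults: 2 donors per group, one
# 12 x 12 mm section each, regions alternating PT/PH.
demo_run <- function() {
  if (is.null(.fixture_env$demo)) {
    cfg <- pipeline_config(seed = 20L, donors_per_group = 2L)
    t0 <- Sys.time()
    .fixture_env$demo <- suppressWarnings(
      run_pipeline(cfg, outdir = NULL, progress = FALSE))
    .fixture_env$demo_elapsed <- as.numeric(Sys.time() - t0, units = "secs")
  }
  .fixture_env$demo
}

demo_elapsed <- function() {
  demo_run()
  .fixture_env$demo_elapsed
}

# Boundary-weighted Ripley statistics under complete spatial randomness:
# 10 seeded patterns of 2000 points in a 20 x 20 mm parenchyma.
csr_ripley_stats <- function() {
  if (is.null(.fixture_env$csr)) {
    par_reg <- rect_poly(0, 0, 20000, 20000)
    meanK <- slope <- numeric(10)
    for (s in 1:10) {
      set.seed(s)
      x <- runif(2000, 0, 20000); y <- runif(2000, 0, 20000)
      rc <- ripley_modified(x, y, par_reg)
      meanK[s] <- mean(rc$curve$K)
      slope[s] <- fractal_dimension(rc)
    }
    .fixture_env$csr <- list(meanK = meanK, slope = slope)
  }
  .fixture_env$csr
}

# Recovery fixture: a single archetype across sections (uniform islet
# density, so the per-section Delaunay-area feature carries no group
# signal), balanced cluster labels, a narrow size distribution and
# well-separated CD45 burden classes -- conditions under which the planted
# labels are identifiable, so clustering recovery is a meaningful test of
# the pipeline rather than of irreducible class overlap.
recovery_overrides <- function() {
  list(idi_fraction = 0.5, p_gamma_given_idi = 0.33,
       p_residual_given_alpha_idi = 0.5, high_burden_fraction_ici = 0.5,
       gcg_deficient_small_fraction = 0.33, ppy_uncinate_fraction = 0.02,
       insulitic_islet_fraction = 0,
       size_log_mean = 8.0, size_log_sd = 0.3,
       cd45_rates = list(baseline = list(intra = 0, peri = 0),
                         high_burden = list(intra = 1.0, peri = 2.0),
                         residual = list(intra = 0.5, peri = 1.0)))
}

recovery_run <- function() {
  if (is.null(.fixture_env$recovery)) {
    cfg <- pipeline_config(seed = 5L, donors_per_group = 8L)
    cfg$cohort$groups <- "AAb"
    cfg$cohort$archetype_overrides <- recovery_overrides()
    .fixture_env$recovery <- suppressWarnings(
      run_pipeline(cfg, outdir = NULL, progress = FALSE))
  }
  .fixture_env$recovery
}

# Align generator truth with the detected islet table of a run.
truth_aligned <- function(run) {
  tb <- run$islet_table
  out <- data.frame(label = rep(NA_character_, nrow(tb)),
                    cd45_total = NA_real_, idi = NA,
                    proins = NA_real_, gcg = NA_real_, ppy = NA_real_,
                    chga = NA_real_, iou = NA_real_)
  for (sid in names(run$synthetic)) {
    sy <- run$synthetic[[sid]]
    rows <- which(tb$section_id == sid)
    m <- match_islets_to_truth(run$sections[[sid]]$islets, sy)
    tr <- sy$truth[m$truth_id, ]
    out$label[rows] <- tr$label
    out$cd45_total[rows] <- tr$cd45_intra + tr$cd45_peri
    out$idi[rows] <- tr$is_idi
    out$proins[rows] <- tr$proins
    out$gcg[rows] <- tr$gcg
    out$ppy[rows] <- tr$ppy
    out$chga[rows] <- tr$chga
    out$iou[rows] <- m$iou
  }
  out
}

# Brute-force Delaunay oracle for small point sets: a triangle belongs to
# the triangulation iff its circumcircle contains no other point; an edge
# belongs iff it is a side of such a triangle (or n == 2).
brute_delaunay <- function(x, y) {
  n <- length(x)
  if (n == 2L) {
    return(list(edges = cbind(1L, 2L),
                lengths = sqrt(diff(x)^2 + diff(y)^2),
                triangles = list()))
  }
  circum <- function(i, j, k) {
    ax <- x[i]; ay <- y[i]; bx <- x[j]; by <- y[j]; cx <- x[k]; cy <- y[k]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) return(NULL)
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    c(ux, uy, sqrt((ax - ux)^2 + (ay - uy)^2))
  }
  tris <- list(); edges <- NULL
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    cc <- circum(i, j, k)
    if (is.null(cc)) next
    others <- setdiff(seq_len(n), c(i, j, k))
    d2 <- (x[others] - cc[1])^2 + (y[others] - cc[2])^2
    if (all(d2 > cc[3]^2 * (1 + 1e-9))) {
      tris[[length(tris) + 1L]] <- list(
        ind = c(i, j, k),
        area = abs((x[j] - x[i]) * (y[k] - y[i]) -
                     (x[k] - x[i]) * (y[j] - y[i])) / 2,
        sides = c(sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2),
                  sqrt((x[j] - x[k])^2 + (y[j] - y[k])^2),
                  sqrt((x[k] - x[i])^2 + (y[k] - y[i])^2)))
      edges <- rbind(edges, c(i, j), c(j, k), c(i, k))
    }
  }
  edges <- unique(edges)
  lens <- sqrt((x[edges[, 1]] - x[edges[, 2]])^2 +
                 (y[edges[, 1]] - y[edges[, 2]])^2)
  list(edges = edges, lengths = lens, triangles = tris)
}

# Reference Delaunay metrics from the oracle, mirroring the retained-edge
# and retained-triangle rules.
brute_delaunay_metrics <- function(x, y, max_radius) {
  bd <- brute_delaunay(x, y)
  n <- length(x)
  out <- data.frame(mean_dist = rep(max_radius, n),
                    mean_area = rep(pi * max_radius^2, n),
                    n_edges = 0L)
  keep <- which(bd$lengths <= max_radius)
  for (i in seq_len(n)) {
    inc <- keep[bd$edges[keep, 1] == i | bd$edges[keep, 2] == i]
    if (length(inc)) {
      out$mean_dist[i] <- mean(bd$lengths[inc])
      out$n_edges[i] <- length(inc)
    }
    tri <- Filter(function(t) i %in% t$ind && all(t$sides <= max_radius),
                  bd$triangles)
    if (length(tri)) out$mean_area[i] <- mean(vapply(tri, `[[`, 0, "area"))
  }
  out
}

skip_if_no_mclust <- function() {
  testthat::skip_if_not_installed("mclust")
}
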