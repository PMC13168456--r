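# Synthetic pancreas-section generator.
#
# Every section is built from a donor archetype: lognormal islet areas
# (truncated at the 1000 um^2 islet definition), perturbed-circle islet
# polygons placed under a chosen spatial law, endocrine cell-type
# "territories" realized as exact-area angular sectors that tile each
# islet, hormone stain polygons nested inside their territory, and CD45 /
# nucleus point patterns planted at archetype rates. All ground truth is
# recorded, so every downstream stage can be tested against known answers.

#' Sample islet areas from a truncated lognormal
#'
#' Draws from the archetype's lognormal area model, truncated below at
#' 1000 um^2 (the operational islet definition), by inverse-CDF sampling so
#' each draw costs one uniform variate.
#'
#' @param archetype a [donor_archetype()].
#' @param n number of islets (>= 1).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return numeric vector of `n` areas in um^2.
#' @export
sample_islet_areas <- function(archetype, n, seed = NULL) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  mu <- archetype$size_log_mean; s <- archetype$size_log_sd
  amin <- archetype$min_islet_area
  if (!is.finite(mu) || s < 0) stop("invalid lognormal parameters")
  if (s == 0) return(rep(max(amin, exp(mu)), n))
  p0 <- stats::plnorm(amin, mu, s)
  u <- stats::runif(n, p0, 1)
  stats::qlnorm(u, mu, s)
}

# Perturbed-circle islet outline: radial Fourier noise on a circle,
# rescaled to the exact target area. Star-shaped about its centre by
# construction (amplitudes bounded by shape_noise < 1).
.islet_outline <- function(area, shape_noise, n_vertices = 64L) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  r <- rep(1, n_vertices)
  if (shape_noise > 0) {
    modes <- 2:5
    w <- stats::runif(length(modes))
    amp <- shape_noise * w / max(sum(w), 1e-12) * stats::runif(1, 0.7, 1)
    ph <- stats::runif(length(modes), 0, 2 * pi)
    for (k in seq_along(modes)) r <- r + amp[k] * cos(modes[k] * th + ph[k])
  }
  a0 <- abs(ring_signed_area(list(x = r * cos(th), y = r * sin(th))))
  s <- sqrt(area / a0)
  ring(s * r * cos(th), s * r * sin(th))
}

#' Place islet polygons inside a parenchyma boundary
#'
#' Generates perturbed-circle outlines for the requested areas and places
#' them, non-overlapping, under one of four spatial laws: complete spatial
#' randomness (`CSR`), a Thomas-style parent/offspring `clustered` process,
#' `half_region` (centroids restricted to the left half), or `uncinate`
#' (centroids restricted to a lower-left sub-box emulating the uncinate
#' process of the pancreas head).
#'
#' @param boundary a `tissue_section` (see [tissue_section()]) or a region.
#' @param areas target islet areas in um^2; each placed polygon has exactly
#'   this area (outline rescaling is exact).
#' @param mode spatial law.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param shape_noise radial perturbation amplitude (0 gives near-circles).
#' @param border_margin minimum distance from polygon to the tissue border,
#'   um; the default 12 keeps all placed islets clear of the 10 um border
#'   exclusion filter. Set small (or 0) to exercise that filter.
#' @param min_gap minimum gap between islet polygons, um.
#' @param max_tries placement attempts per islet before failing.
#' @param n_vertices vertices per islet outline.
#' @return list of rings, in the order of `areas`; each ring carries the
#'   generation centre as attribute `"centre"`.
#' @export
place_islets <- function(boundary, areas,
                         mode = c("CSR", "clustered", "half_region", "uncinate"),
                         seed = NULL, shape_noise = 0.08, border_margin = 12,
                         min_gap = 5, max_tries = 500L, n_vertices = 64L) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  par_reg <- if (inherits(boundary, "tissue_section")) boundary$parenchyma else as_region(boundary)
  if (length(par_reg) == 0L) stop("empty parenchyma boundary")
  if (any(!is.finite(areas)) || any(areas <= 0)) stop("invalid areas")
  bb <- region_bbox(par_reg)
  xr <- bb[c(1, 3)]; yr <- bb[c(2, 4)]
  if (mode == "half_region") xr[2] <- xr[1] + diff(xr) / 2
  if (mode == "uncinate") {
    xr[2] <- xr[1] + 0.40 * diff(xr)
    yr[1] <- yr[1] + 0.55 * diff(yr)
  }
  n_par <- 0L; parents <- NULL
  if (mode == "clustered") {
    n_par <- max(1L, round(length(areas) / 25))
    parents <- cbind(stats::runif(n_par, xr[1], xr[2]),
                     stats::runif(n_par, yr[1], yr[2]))
  }
  ord <- order(areas, decreasing = TRUE)  # pack large islets first
  out <- vector("list", length(areas))
  acc_x <- numeric(0); acc_y <- numeric(0); acc_r <- numeric(0)
  for (i in ord) {
    shape <- .islet_outline(areas[i], shape_noise, n_vertices)
    rmax <- sqrt(max(shape$x^2 + shape$y^2))
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      if (mode == "clustered") {
        p <- parents[sample.int(n_par, 1L), ]
        cx <- stats::rnorm(1, p[1], 500); cy <- stats::rnorm(1, p[2], 500)
        if (cx < xr[1] || cx > xr[2] || cy < yr[1] || cy > yr[2]) next
      } else {
        cx <- stats::runif(1, xr[1], xr[2]); cy <- stats::runif(1, yr[1], yr[2])
      }
      if (!pts_in_region(cx, cy, par_reg)) next
      if (dist_to_boundary(cx, cy, par_reg) < rmax + border_margin) next
      if (length(acc_x) &&
          any((acc_x - cx)^2 + (acc_y - cy)^2 < (acc_r + rmax + min_gap)^2)) next
      out[[i]] <- structure(ring(shape$x + cx, shape$y + cy),
                            centre = c(cx, cy))
      acc_x <- c(acc_x, cx); acc_y <- c(acc_y, cy); acc_r <- c(acc_r, rmax)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("islet packing failed: placed ", sum(!vapply(out, is.null, TRUE)),
           " of ", length(areas), " islets before exhausting ", max_tries,
           " tries (boundary too crowded?)")
  }
  out
}

# Split a star-shaped polygon (vertices in angular order about `centre`)
# into consecutive fans with exactly the requested area fractions.
# Boundary points are interpolated along edges, so wedge areas are exact
# up to floating rounding.
.fan_split <- function(r, centre, fractions) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  cx <- centre[1]; cy <- centre[2]
  x <- r$x - cx; y <- r$y - cy
  n <- length(x)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  tri <- (x * y2 - x2 * y) / 2           # signed fan triangle areas
  if (any(tri <= 0) && any(tri >= 0) && sign(sum(tri)) < 0) {
    # normalize to positive traversal
    idx <- c(1, n:2)
    return(.fan_split(list(x = r$x[idx], y = r$y[idx]), centre, fractions))
  }
  tot <- sum(tri)
  cum <- c(0, cumsum(tri))
  targets <- tot * cumsum(fractions)[-length(fractions)]
  # boundary points (first boundary is vertex 1)
  bx <- numeric(length(targets)); by <- numeric(length(targets))
  bk <- integer(length(targets))
  for (j in seq_along(targets)) {
    k <- findInterval(targets[j], cum, rightmost.closed = TRUE)
    k <- min(max(k, 1L), n)
    u <- (targets[j] - cum[k]) / tri[k]
    u <- min(max(u, 0), 1)
    bx[j] <- x[k] + u * (x2[k] - x[k])
    by[j] <- y[k] + u * (y2[k] - y[k])
    bk[j] <- k
  }
  starts_k <- c(1L, bk)
  starts_x <- c(x[1], bx); starts_y <- c(y[1], by)
  ends_k <- c(bk, n)
  ends_x <- c(bx, x[1]); ends_y <- c(by, y[1])
  wedges <- vector("list", length(fractions))
  for (j in seq_along(fractions)) {
    ks <- starts_k[j]; ke <- ends_k[j]
    mid <- if (j == length(fractions)) {
      if (ks < n) (ks + 1L):n else integer(0)
    } else if (ke > ks) (ks + 1L):ke else integer(0)
    wx <- c(0, starts_x[j], x[mid], ends_x[j])
    wy <- c(0, starts_y[j], y[mid], ends_y[j])
    # drop consecutive duplicate vertices (boundary exactly on a vertex)
    keep <- c(TRUE, abs(diff(wx)) + abs(diff(wy)) > 1e-12)
    wx <- wx[keep]; wy <- wy[keep]
    if (length(wx) < 3L) { wx <- c(0, starts_x[j], ends_x[j]); wy <- c(0, starts_y[j], ends_y[j]) }
    wedges[[j]] <- ring(wx + cx, wy + cy)
  }
  wedges
}

#' Draw the endocrine composition of one islet
#'
#' Cell-type territory fractions (beta, alpha, delta, gamma) are drawn
#' around the archetype's one-phase association curves
#' `f(A) = plateau + span * exp(-k * A)` with additive noise, then
#' renormalized to tile the islet; deficiency branches (insulin-deficient,
#' GCG-deficient, gamma/PPY-dominant) pin the respective territory below
#' the 1% phenotype boundary before renormalization, so planted phenotypes
#' are exact. The archetype cluster label records which branch generated
#' the islet, for recovery tests.
#'
#' @param archetype a [donor_archetype()].
#' @param islet_area islet area in um^2 (>= 1000).
#' @param seed optional integer seed.
#' @return list: `territories` (named beta/alpha/delta/gamma fractions
#'   summing to 1), `fractions` (named planted stain fractions of islet
#'   area for all 8 hormones plus `proins_hi` and `chga`), `label`
#'   (archetype cluster, one of I, II, III, IV, V-A, V-BC), `is_idi`,
#'   `burden` (CD45 burden class), `gamma_dominant`.
#' @export
assign_composition <- function(archetype, islet_area, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (islet_area < archetype$min_islet_area)
    stop("islet_area below the ", archetype$min_islet_area, " um^2 islet definition")
  a <- archetype
  cc <- a$composition_curves
  curve <- function(h) {
    p <- cc[[h]]; p$plateau + p$span * exp(-p$k * islet_area)
  }
  base <- c(beta = curve("beta"), alpha = curve("alpha"),
            delta = curve("delta"), gamma = curve("gamma"))
  base <- pmin(pmax(base + stats::rnorm(4, 0, a$composition_noise_sd), 0.002), 1)
  defmax <- a$deficient_max_fraction
  rdef <- function() stats::runif(1, 0.001, defmax)
  is_idi <- stats::runif(1) < a$idi_fraction
  gamma_dom <- FALSE
  deficient <- character(0)
  if (!is_idi) {
    p_gcgdef <- a$gcg_deficient_small_fraction *
      (if (islet_area < 3000) 1 else 0.3)
    gcg_def <- stats::runif(1) < p_gcgdef
    ppy_dom <- stats::runif(1) < a$ppy_uncinate_fraction
    # immune engagement is drawn independently of the alpha-deficiency
    # branch: beta+alpha- (III) islets carry the same burden mix, which in
    # the pancreas head dominates the >= 1-CD45 islet fraction
    high <- stats::runif(1) < a$high_burden_fraction_ici
    burden <- if (high) "high_burden" else "baseline"
    if (gcg_def || ppy_dom) {
      label <- "III"
      base["alpha"] <- rdef(); deficient <- "alpha"
      if (ppy_dom) { base["gamma"] <- a$gamma_dominant_fraction; gamma_dom <- TRUE }
    } else {
      label <- if (high) "II" else "I"
    }
  } else {
    base["beta"] <- rdef(); deficient <- "beta"
    if (stats::runif(1) < a$p_gamma_given_idi) {
      label <- "IV"
      base["alpha"] <- rdef(); deficient <- c(deficient, "alpha")
      base["gamma"] <- a$gamma_dominant_fraction; gamma_dom <- TRUE
      burden <- "baseline"
    } else {
      base["alpha"] <- min(1, curve("alpha") + curve("beta") +
                             stats::rnorm(1, 0, a$composition_noise_sd))
      if (stats::runif(1) < a$p_residual_given_alpha_idi) {
        label <- "V-A"; burden <- "residual"
      } else {
        label <- "V-BC"; burden <- "baseline"
      }
    }
  }
  # renormalize to tile the islet, preserving pinned deficient territories
  free <- setdiff(names(base), deficient)
  rem <- 1 - sum(base[deficient])
  s <- sum(base[free])
  # renormalization to a full tiling is systematic (the curves describe
  # relative composition); gamma-dominant branches overwrite one territory
  # and always renormalize. Warn only on draws far outside the noise band.
  if (!gamma_dom && sum(base) > 1.25)
    warning("territory fractions summed to ", signif(sum(base), 4),
            "; check composition curves")
  base[free] <- base[free] * rem / s
  chga <- if (gamma_dom && label == "IV") {
    min(max(stats::rnorm(1, a$chga_fraction_low$mean, a$chga_fraction_low$sd), 0.02), 0.09)
  } else {
    min(max(stats::rnorm(1, a$chga_fraction$mean, a$chga_fraction$sd), 0.85), 0.99)
  }
  sr <- a$stain_ratios
  fr <- c(chga = chga,
          proins = unname(base["beta"]),
          proins_hi = unname(base["beta"]) * sr$proins_hi,
          ins = unname(base["beta"]) * sr$ins,
          iapp = unname(base["beta"]) * sr$iapp,
          gcg = unname(base["alpha"]),
          progcg = unname(base["alpha"]) * sr$progcg,
          sst = unname(base["delta"]),
          ppy = unname(base["gamma"]))
  list(territories = base, fractions = fr, label = label, is_idi = is_idi,
       burden = burden, gamma_dominant = gamma_dom)
}

# Realize stain polygons for one islet from its composition: territories
# are consecutive exact-area fans; each hormone is its territory or a
# scaled-down copy nested inside it; CHGA is a scaled copy of the islet.
.plant_stains <- function(islet_ring, comp) {
  centre <- attr(islet_ring, "centre")
  if (is.null(centre)) centre <- ring_centroid(islet_ring)
  w <- .fan_split(islet_ring, centre, comp$territories)
  names(w) <- names(comp$territories)
  sc <- function(r, f_target, f_territory) {
    s <- sqrt(f_target / f_territory)
    scale_ring(r, min(s, 1), centre[1], centre[2])
  }
  fr <- comp$fractions
  t <- comp$territories
  list(CHGA   = sc(islet_ring, fr[["chga"]], 1),
       ProINS = w$beta,
       ProINS_hi = sc(w$beta, fr[["proins_hi"]], t[["beta"]]),
       INS    = sc(w$beta, fr[["ins"]], t[["beta"]]),
       IAPP   = sc(w$beta, fr[["iapp"]], t[["beta"]]),
       GCG    = w$alpha,
       ProGCG = sc(w$alpha, fr[["progcg"]], t[["alpha"]]),
       SST    = w$delta,
       PPY    = w$gamma)
}

# uniform points in a region by bbox rejection
.runif_region <- function(n, reg, boundary_inside = FALSE) {
  if (n <= 0) return(cbind(x = numeric(0), y = numeric(0)))
  bb <- region_bbox(reg)
  got_x <- numeric(0); got_y <- numeric(0)
  guard <- 0L
  while (length(got_x) < n && guard < 1000L) {
    m <- max(32L, 4L * (n - length(got_x)))
    px <- stats::runif(m, bb[1], bb[3]); py <- stats::runif(m, bb[2], bb[4])
    ok <- pts_in_region(px, py, reg, boundary_inside = boundary_inside)
    got_x <- c(got_x, px[ok]); got_y <- c(got_y, py[ok])
    guard <- guard + 1L
  }
  if (length(got_x) < n) stop("rejection sampling failed: degenerate region?")
  cbind(x = got_x[seq_len(n)], y = got_y[seq_len(n)])
}

#' Plant CD45 and nucleus point patterns around one islet
#'
#' Homogeneous Poisson processes at archetype rates in the intra-islet and
#' peri-islet (20 um annulus) compartments. Peri points falling nearer to a
#' neighboring islet than to this one are thinned out (the neighbor's own
#' process repopulates its side), matching the watershed attribution used
#' in the analysis. Insulitic plants receive at least
#' `insulitis_min_cells` total CD45 cells. Nuclei are the CD45 points (a
#' CD45+ cell has a nucleus) plus a background nucleus process.
#'
#' @param islet a ring (the islet polygon).
#' @param archetype a [donor_archetype()].
#' @param seed optional integer seed.
#' @param burden CD45 burden class: `"baseline"`, `"high_burden"` or
#'   `"residual"` (residual islets retain at least one cell).
#' @param insulitic plant an insulitic burden (>= 15 associated cells).
#' @param neighbors list of neighboring islet rings competing for the
#'   peri-islet region.
#' @param tissue optional tissue region clipping the peri compartment.
#' @param peri_width annulus width in um (20, the peri-islet definition).
#' @return list with data.frames `cd45` and `nuclei` (columns `x`, `y`,
#'   `compartment`) and the realized counts `n_intra`, `n_peri`.
#' @export
scatter_cd45 <- function(islet, archetype, seed = NULL,
                         burden = c("baseline", "high_burden", "residual"),
                         insulitic = FALSE, neighbors = list(), tissue = NULL,
                         peri_width = 20) {
  burden <- match.arg(burden)
  if (!is.null(seed)) set.seed(seed)
  a <- archetype
  rates <- a$cd45_rates[[burden]]
  A_islet <- region_area(islet)
  peri <- poly_op(poly_buffer(islet, peri_width), islet, "minus")
  if (!is.null(tissue)) peri <- poly_op(peri, tissue, "intersection")
  A_peri <- region_area(peri)
  n_intra <- stats::rpois(1, rates$intra * A_islet / 1000)
  n_peri <- stats::rpois(1, rates$peri * A_peri / 1000)
  if (insulitic) {
    tot <- a$insulitis_min_cells + stats::rpois(1, a$insulitis_extra_mean)
    k <- stats::rbinom(1, tot, 0.4)
    n_intra <- max(n_intra, k)
    n_peri <- max(n_peri, tot - k)
  }
  pin <- .runif_region(n_intra, islet)
  pper <- if (n_peri > 0) .runif_region(n_peri, peri) else cbind(x = numeric(0), y = numeric(0))
  # thin peri points attributed to a nearer neighbor
  if (n_peri > 0 && length(neighbors)) {
    d_own <- dist_to_boundary(pper[, 1], pper[, 2], islet)
    keep <- rep(TRUE, nrow(pper))
    for (nb in neighbors) {
      inside_nb <- pts_in_region(pper[, 1], pper[, 2], nb)
      d_nb <- dist_to_boundary(pper[, 1], pper[, 2], nb)
      keep <- keep & !inside_nb & (d_own <= d_nb)
    }
    pper <- pper[keep, , drop = FALSE]
  }
  if (burden == "residual" && nrow(pin) + nrow(pper) == 0L && region_area(peri) > 0) {
    pper <- .runif_region(1L, peri)
  }
  nin <- nrow(pin); nper <- nrow(pper)
  bg_in <- .runif_region(stats::rpois(1, a$nuclei_density * A_islet / 1000), islet)
  bg_pe_n <- stats::rpois(1, a$nuclei_density * A_peri / 1000)
  bg_pe <- if (bg_pe_n > 0) .runif_region(bg_pe_n, peri) else cbind(x = numeric(0), y = numeric(0))
  cd45 <- data.frame(x = c(pin[, 1], pper[, 1]), y = c(pin[, 2], pper[, 2]),
                     compartment = rep(c("intra", "peri"), c(nin, nper)))
  nuc <- data.frame(
    x = c(cd45$x, bg_in[, 1], bg_pe[, 1]),
    y = c(cd45$y, bg_in[, 2], bg_pe[, 2]),
    compartment = c(cd45$compartment, rep("intra", nrow(bg_in)),
                    rep("peri", nrow(bg_pe))))
  list(cd45 = cd45, nuclei = nuc, n_intra = nin, n_peri = nper)
}

#' Construct a tissue section container
#'
#' @param section_id,donor_id identifiers.
#' @param group donor group; @param region pancreas region.
#' @param tissue,parenchyma regions (lists of rings), um coordinates;
#'   parenchyma must lie within tissue.
#' @param pixel_size um per pixel when raster data accompany the section.
#' @return object of class `tissue_section`.
#' @export
tissue_section <- function(section_id, donor_id = section_id,
                           group = "Ctrl", region = "PT",
                           tissue, parenchyma = tissue, pixel_size = NA_real_) {
  tissue <- as_region(tissue); parenchyma <- as_region(parenchyma)
  if (region_area(tissue) <= 0 || region_area(parenchyma) <= 0)
    stop("tissue and parenchyma must have positive area")
  structure(list(section_id = section_id, donor_id = donor_id,
                 group = group, region = region,
                 tissue = tissue, parenchyma = parenchyma,
                 pixel_size = pixel_size),
            class = "tissue_section")
}

#' Generate one synthetic pancreas section
#'
#' The full generator: areas, placement (uncinate regionalization of
#' PPY-dominant islets in PH sections), composition, stain polygons, CD45
#' and nucleus point patterns, all with recorded ground truth.
#'
#' @param group donor group; @param region pancreas region.
#' @param seed integer seed (required: sections are reproducible objects).
#' @param width_mm,height_mm rectangular parenchyma dimensions.
#' @param n_islets override the archetype islet count
#'   (`round(density * area)` by default).
#' @param archetype optional pre-built [donor_archetype()].
#' @param placement spatial law for non-uncinate islets.
#' @param section_id,donor_id identifiers.
#' @return object of class `synthetic_section`: fields `section`
#'   (tissue_section), `islets` (list of rings), `stains` (per-hormone list
#'   of per-islet rings), `truth` (data.frame of planted properties),
#'   `points` (data.frame x, y, kind, islet_id, compartment), `seed`.
#' @export
synth_section <- function(group = "Ctrl", region = "PT", seed = 1L,
                          width_mm = 12, height_mm = 12, n_islets = NULL,
                          archetype = NULL, placement = "CSR",
                          section_id = paste0(group, "_", region, "_s", seed),
                          donor_id = paste0(group, "_d", seed)) {
  if (is.null(archetype)) archetype <- donor_archetype(group, region)
  set.seed(seed)
  W <- width_mm * 1000; H <- height_mm * 1000
  rect <- rect_poly(0, 0, W, H)
  sec <- tissue_section(section_id, donor_id, group, region, tissue = rect)
  n <- if (is.null(n_islets)) round(archetype$islet_density * width_mm * height_mm) else n_islets
  areas <- sample_islet_areas(archetype, n)
  comps <- lapply(areas, function(a) assign_composition(archetype, a))
  unc <- vapply(comps, `[[`, logical(1), "gamma_dominant") & region == "PH"
  islets <- vector("list", n)
  if (any(unc)) {
    islets[unc] <- place_islets(sec, areas[unc], mode = "uncinate",
                                shape_noise = archetype$shape_noise)
    # place the rest avoiding the uncinate islets: seed accepted set
    rest <- place_islets(sec, areas[!unc], mode = placement,
                         shape_noise = archetype$shape_noise)
    # resolve rare overlaps between the two passes by nudged re-placement
    centres_u <- t(vapply(islets[unc], function(r) attr(r, "centre"), numeric(2)))
    rmax_u <- vapply(islets[unc], function(r) {
      c0 <- attr(r, "centre"); sqrt(max((r$x - c0[1])^2 + (r$y - c0[2])^2))
    }, numeric(1))
    ri <- which(!unc)
    for (k in seq_along(rest)) {
      r <- rest[[k]]; c0 <- attr(r, "centre")
      rmax <- sqrt(max((r$x - c0[1])^2 + (r$y - c0[2])^2))
      tries <- 0L
      while (any(sqrt((centres_u[, 1] - c0[1])^2 + (centres_u[, 2] - c0[2])^2) <
                 rmax_u + rmax + 5) && tries < 200L) {
        c0 <- c(stats::runif(1, rmax + 12, W - rmax - 12),
                stats::runif(1, rmax + 12, H - rmax - 12))
        tries <- tries + 1L
      }
      rest[[k]] <- structure(ring(r$x - attr(r, "centre")[1] + c0[1],
                                  r$y - attr(r, "centre")[2] + c0[2]),
                             centre = c0)
    }
    islets[!unc] <- rest
  } else {
    islets <- place_islets(sec, areas, mode = placement,
                           shape_noise = archetype$shape_noise)
  }
  hormones <- c("CHGA", "ProINS", "ProINS_hi", "INS", "IAPP",
                "GCG", "ProGCG", "SST", "PPY")
  stains <- stats::setNames(rep(list(vector("list", n)), length(hormones)), hormones)
  centres <- t(vapply(islets, function(r) attr(r, "centre"), numeric(2)))
  rmaxs <- vapply(seq_len(n), function(i) {
    sqrt(max((islets[[i]]$x - centres[i, 1])^2 + (islets[[i]]$y - centres[i, 2])^2))
  }, numeric(1))
  insulitic <- stats::runif(n) < archetype$insulitic_islet_fraction
  pts <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    st <- .plant_stains(islets[[i]], comps[[i]])
    for (h in hormones) stains[[h]][[i]] <- st[[h]]
    nb <- which(sqrt((centres[, 1] - centres[i, 1])^2 +
                     (centres[, 2] - centres[i, 2])^2) < rmaxs + rmaxs[i] + 45)
    nb <- setdiff(nb, i)
    sc <- scatter_cd45(islets[[i]], archetype, burden = comps[[i]]$burden,
                       insulitic = insulitic[i], neighbors = islets[nb],
                       tissue = sec$tissue)
    fr <- comps[[i]]$fractions
    truth[[i]] <- data.frame(
      islet_id = i, area = areas[i],
      x = centres[i, 1], y = centres[i, 2],
      label = comps[[i]]$label, is_idi = comps[[i]]$is_idi,
      burden = comps[[i]]$burden, insulitic_planted = insulitic[i],
      chga = fr[["chga"]], proins = fr[["proins"]], proins_hi = fr[["proins_hi"]],
      ins = fr[["ins"]], iapp = fr[["iapp"]], gcg = fr[["gcg"]],
      progcg = fr[["progcg"]], sst = fr[["sst"]], ppy = fr[["ppy"]],
      cd45_intra = sc$n_intra, cd45_peri = sc$n_peri)
    p1 <- sc$cd45; p2 <- sc$nuclei
    pts[[i]] <- rbind(
      if (nrow(p1)) data.frame(x = p1$x, y = p1$y, kind = "cd45",
                               islet_id = i, compartment = p1$compartment),
      data.frame(x = p2$x, y = p2$y, kind = "nucleus",
                 islet_id = i, compartment = p2$compartment))
  }
  structure(list(section = sec,
                 islets = islets,
                 stains = stains,
                 truth = do.call(rbind, truth),
                 points = do.call(rbind, pts),
                 seed = seed,
                 archetype = archetype),
            class = "synthetic_section")
}

#' @export
print.synthetic_section <- function(x, ...) {
  cat("<synthetic_section> ", x$section$section_id, ": ",
      length(x$islets), " islets, ",
      sum(x$points$kind == "cd45"), " CD45+ cells, seed ", x$seed, "\n", sep = "")
  invisible(x)
}
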