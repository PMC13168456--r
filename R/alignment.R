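# Image alignment and islet object construction.
#
# The moving (stain) image is registered to the base (CD45) image with an
# affine transform estimated at a coarse working resolution (default 5 um),
# after which all geometry lives in the base frame. Islet objects are the
# merged hormone-stain regions: union, split into components, interior
# holes filled, sub-1000 um^2 objects removed, and objects within 10 um of
# the tissue border removed.

# block-mean downsample a raster to (approximately) a working resolution
.downsample <- function(m, pixel_size, working_resolution) {
  k <- max(1L, round(working_resolution / pixel_size))
  if (k == 1L) {
    attr(m, "pixel_size") <- pixel_size
    return(m)
  }
  ny <- nrow(m) %/% k * k; nx <- ncol(m) %/% k * k
  m <- m[seq_len(ny), seq_len(nx), drop = FALSE]
  mm <- matrix(0, ny %/% k, nx %/% k)
  for (dy in seq_len(k)) for (dx in seq_len(k)) {
    mm <- mm + m[seq(dy, ny, by = k), seq(dx, nx, by = k), drop = FALSE]
  }
  out <- mm / k^2
  attr(out, "pixel_size") <- pixel_size * k
  out
}

# bilinear sample of raster m at um coordinates (x, y); outside -> 0
.sample_bilinear <- function(m, px, x, y) {
  cj <- x / px + 0.5; ci <- y / px + 0.5
  j0 <- floor(cj); i0 <- floor(ci)
  fj <- cj - j0; fi <- ci - i0
  ny <- nrow(m); nx <- ncol(m)
  get <- function(i, j) {
    ok <- i >= 1 & i <= ny & j >= 1 & j <= nx
    v <- numeric(length(i))
    v[ok] <- m[cbind(i[ok], j[ok])]
    v
  }
  get(i0, j0) * (1 - fi) * (1 - fj) + get(i0, j0 + 1) * (1 - fi) * fj +
    get(i0 + 1, j0) * fi * (1 - fj) + get(i0 + 1, j0 + 1) * fi * fj
}

#' Estimate the affine transform aligning a moving raster to a base raster
#'
#' Minimizes the mean squared intensity mismatch between the base image and
#' the warped moving image on grids downsampled to `working_resolution`
#' (default 5 um), over translation, rotation, anisotropic scale and shear,
#' using Nelder-Mead from multiple starts (identity and intensity-centroid
#' initializations, plus jittered restarts).
#'
#' @param moving,base raster matrices with a `pixel_size` attribute (or
#'   supply `pixel_size`).
#' @param working_resolution optimization resolution in um (>= pixel size).
#' @param pixel_size um/px of both rasters if not carried as an attribute.
#' @param n_starts number of optimization starts.
#' @param max_iter Nelder-Mead iteration cap per start.
#' @return list of class `affine_fit`: `transform` (2x3, moving -> base,
#'   um), `params`, `residual` (RMS intensity mismatch), `converged`.
#' @export
estimate_affine <- function(moving, base, working_resolution = 5,
                            pixel_size = attr(base, "pixel_size"),
                            n_starts = 4L, max_iter = 400L) {
  if (is.null(pixel_size)) stop("pixel_size metadata missing")
  if (sum(moving) == 0 || sum(base) == 0) stop("empty raster")
  if (working_resolution < pixel_size)
    stop("working_resolution must be >= pixel size")
  # objective at one pyramid level: mean squared mismatch over the dilated
  # support of either image (empty background contributes no gradient)
  make_obj <- function(res) {
    b <- .downsample(base, pixel_size, res)
    mv <- .downsample(moving, pixel_size, res)
    px <- attr(b, "pixel_size")
    ny <- nrow(b); nx <- ncol(b)
    gx <- rep((seq_len(nx) - 0.5) * px, each = ny)
    gy <- rep((seq_len(ny) - 0.5) * px, times = nx)
    bv <- as.vector(b)
    supp <- bv > 0 | as.vector(mv) > 0
    # dilate the support by ~12 coarse pixels via a grid-rounding trick
    cell <- 12 * px
    keyed <- unique(paste(round(gx[supp] / cell), round(gy[supp] / cell)))
    near <- paste(round(gx / cell), round(gy / cell)) %in% keyed
    gx <- gx[near]; gy <- gy[near]; bv <- bv[near]
    centre <- c(sum(gx * bv), sum(gy * bv)) / max(sum(bv), 1e-12)
    list(centre = centre, mv = mv, px = px,
         f = function(p, centre) {
           A <- affine_transform(p[1], p[2], p[3], exp(p[4]), exp(p[5]), p[6],
                                 centre = centre)
           q <- apply_affine(invert_affine(A), gx, gy)
           w <- .sample_bilinear(mv, px, q[, 1], q[, 2])
           mean((w - bv)^2)
         })
  }
  # intensity-centroid shift initialization at the coarse level
  coarse <- make_obj(4 * working_resolution)
  mvv <- as.vector(coarse$mv); px_c <- coarse$px
  mgx <- rep((seq_len(ncol(coarse$mv)) - 0.5) * px_c, each = nrow(coarse$mv))
  mgy <- rep((seq_len(nrow(coarse$mv)) - 0.5) * px_c, times = ncol(coarse$mv))
  mcent <- c(sum(mgx * mvv), sum(mgy * mvv)) / sum(mvv)
  shift <- coarse$centre - mcent
  starts <- list(c(0, 0, 0, 0, 0, 0), c(shift, 0, 0, 0, 0))
  if (n_starts > 2L) {
    for (k in seq_len(n_starts - 2L)) {
      starts[[2L + k]] <- c(shift + c((-1)^k * 2 * px_c,
                                      (-1)^(k %/% 2) * 2 * px_c),
                            0.02 * (-1)^k, 0, 0, 0)
    }
  }
  best <- NULL
  for (s in starts) {
    fit <- stats::optim(s, coarse$f, centre = coarse$centre,
                        method = "Nelder-Mead",
                        control = list(maxit = max_iter, reltol = 1e-10))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # refine the winner at the working resolution
  fine <- make_obj(working_resolution)
  best <- stats::optim(best$par, fine$f, centre = coarse$centre,
                       method = "Nelder-Mead",
                       control = list(maxit = max_iter, reltol = 1e-10))
  centre <- coarse$centre
  p <- best$par
  A <- affine_transform(p[1], p[2], p[3], exp(p[4]), exp(p[5]), p[6],
                        centre = centre)
  structure(list(transform = A,
                 params = list(tx = p[1], ty = p[2], theta = p[3],
                               sx = exp(p[4]), sy = exp(p[5]), shear = p[6],
                               centre = centre),
                 residual = sqrt(best$value),
                 converged = best$convergence == 0),
            class = "affine_fit")
}

#' @export
print.affine_fit <- function(x, ...) {
  cat("<affine_fit> RMS residual ", signif(x$residual, 4),
      if (x$converged) " (converged)\n" else " (NOT converged)\n", sep = "")
  print(round(x$transform, 6))
  invisible(x)
}

# decompose a labelled mask component into exact pixel-boundary polygons:
# horizontal runs become rectangles, unioned into a region
.pixels_to_region <- function(idx_ij, pixel_size, origin) {
  o <- order(idx_ij[, 1], idx_ij[, 2])
  ii <- idx_ij[o, 1]; jj <- idx_ij[o, 2]
  newrun <- c(TRUE, diff(jj) != 1L | diff(ii) != 0L)
  rid <- cumsum(newrun)
  j0 <- jj[newrun]; i0 <- ii[newrun]
  j1 <- vapply(split(jj, rid), max, numeric(1))
  rects <- lapply(seq_along(j0), function(k) {
    rect_poly(origin[1] + (j0[k] - 1) * pixel_size,
              origin[2] + (i0[k] - 1) * pixel_size,
              origin[1] + j1[k] * pixel_size,
              origin[2] + i0[k] * pixel_size)
  })
  poly_union_all(rects)
}

# connected-component labelling (4-connectivity) of a logical matrix,
# iterative flood fill via run merging
.label_components <- function(mask) {
  if (requireNamespace("EBImage", quietly = TRUE))
    return(EBImage::bwlabel(mask * 1))
  stop("EBImage is required for connected-component labelling")
}

#' Segment positively stained regions from a raster
#'
#' Thresholds the raster, labels connected components at the working
#' resolution, vectorizes each component to its exact pixel-boundary
#' polygon, and drops components below the minimum area (default 50 um^2,
#' the stained-region detection floor).
#'
#' @param raster matrix with `pixel_size`/`origin` attributes.
#' @param intensity_threshold pixels strictly above this are positive.
#' @param working_resolution resolution for component finding, um (raster
#'   is block-averaged down to it if coarser than the pixel size).
#' @param min_area minimum region area in um^2.
#' @param pixel_size,origin metadata overrides.
#' @return list of regions (each a list of rings), with attribute `areas`.
#' @export
segment_stain_regions <- function(raster, intensity_threshold = 0.5,
                                  working_resolution = NULL, min_area = 50,
                                  pixel_size = attr(raster, "pixel_size"),
                                  origin = attr(raster, "origin")) {
  if (is.null(pixel_size)) stop("pixel_size metadata missing")
  if (is.null(origin)) origin <- c(0, 0)
  rng <- range(raster)
  if (intensity_threshold < rng[1] - 1 || intensity_threshold > rng[2] + 1)
    stop("threshold outside the raster intensity range")
  if (!is.null(working_resolution) && working_resolution > pixel_size) {
    raster <- .downsample(raster, pixel_size, working_resolution)
    pixel_size <- attr(raster, "pixel_size")
  }
  mask <- raster > intensity_threshold
  if (!any(mask)) return(structure(list(), areas = numeric(0)))
  lab <- .label_components(mask)
  n_px_min <- min_area / pixel_size^2
  tab <- tabulate(lab[lab > 0])
  keep <- which(tab >= n_px_min)
  out <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    idx <- which(lab == keep[k], arr.ind = TRUE)
    out[[k]] <- .pixels_to_region(idx, pixel_size, origin)
  }
  areas <- vapply(out, region_area, numeric(1))
  ok <- areas >= min_area
  structure(out[ok], areas = areas[ok])
}

#' Build islet objects from per-hormone stain regions
#'
#' Implements the islet delineation rule: union of the (six) hormone stain
#' regions, split into connected components, interior holes filled to make
#' contiguous objects, components below `min_area` (1000 um^2) removed,
#' and components closer than `border_distance` (10 um) to the tissue
#' border removed. Survivors get the full shape-descriptor bundle.
#'
#' @param stain_regions named list (one entry per hormone) of ring lists or
#'   regions, all in the base frame.
#' @param section a `tissue_section` (for the border filter). Optional:
#'   `NULL` skips the border filter.
#' @param min_area minimum filled component area, um^2.
#' @param border_distance minimum polygon-to-tissue-border distance, um.
#' @param min_solidity optional artifact rule filter: drop objects with
#'   solidity below this (disabled by default).
#' @return object of class `islet_set`: `polygons` (list of rings) and
#'   `table` (one row per islet with id, area, perimeter, centroid, axis
#'   lengths, aspect_ratio, solidity, circularity, equiv_diameter,
#'   sphere_volume, border_distance).
#' @export
build_islet_objects <- function(stain_regions, section = NULL,
                                min_area = 1000, border_distance = 10,
                                min_solidity = NULL) {
  if (length(stain_regions) == 0L) stop("empty stain set")
  rings <- list()
  for (h in seq_along(stain_regions)) {
    s <- stain_regions[[h]]
    if (is.null(s)) next
    if (!is.null(s$x)) s <- list(s)
    for (r in s) if (!is.null(r)) rings <- c(rings, as_region(r))
  }
  if (length(rings) == 0L) stop("empty stain set")
  merged <- poly_union_all(rings)
  filled <- fill_holes(merged)
  drop_stats <- c(components = length(filled), size_filtered = 0L,
                  border_filtered = 0L, solidity_filtered = 0L)
  areas <- vapply(filled, function(r) abs(ring_signed_area(r)), numeric(1))
  keep <- areas >= min_area
  drop_stats["size_filtered"] <- sum(!keep)
  filled <- filled[keep]
  if (!is.null(section) && length(filled)) {
    bd <- vapply(filled, function(r)
      poly_boundary_distance(r, section$tissue), numeric(1))
    keep <- bd >= border_distance
    drop_stats["border_filtered"] <- sum(!keep)
    filled <- filled[keep]
    bd <- bd[keep]
  } else {
    bd <- rep(NA_real_, length(filled))
  }
  shp <- lapply(filled, compute_shape)
  if (!is.null(min_solidity) && length(filled)) {
    keep <- vapply(shp, `[[`, numeric(1), "solidity") >= min_solidity
    drop_stats["solidity_filtered"] <- sum(!keep)
    filled <- filled[keep]; shp <- shp[keep]; bd <- bd[keep]
  }
  tab <- if (length(filled)) {
    cbind(data.frame(islet_id = seq_along(filled)),
          do.call(rbind, lapply(shp, as.data.frame)),
          data.frame(border_distance = bd))
  } else {
    data.frame(islet_id = integer(0))
  }
  structure(list(polygons = filled, table = tab, dropped = drop_stats),
            class = "islet_set")
}

#' @export
print.islet_set <- function(x, ...) {
  cat("<islet_set> ", length(x$polygons), " islets (dropped: ",
      paste(names(x$dropped), x$dropped, sep = "=", collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Spectral unmixing of brightfield stains
#'
#' Converts RGB transmitted-light intensities to optical densities
#' (Beer-Lambert, `OD = -log10(I / I0)`) and projects onto the supplied
#' stain OD vectors by pseudo-inverse; negative densities are clipped to 0.
#'
#' @param rgb numeric array `h x w x 3` (or `n x 3` matrix) of intensities
#'   in `[0, 255]`.
#' @param stain_od_vectors matrix with one column per stain (3 rows, RGB
#'   optical densities); 2-3 linearly independent columns.
#' @param i0 incident intensity (default 255).
#' @return array `h x w x n_stains` (or `n x n_stains` matrix) of stain
#'   densities.
#' @export
unmix_stains <- function(rgb, stain_od_vectors, i0 = 255) {
  V <- as.matrix(stain_od_vectors)
  if (qr(V)$rank < ncol(V)) stop("stain OD vectors are rank deficient")
  dims <- dim(rgb)
  flat <- if (length(dims) == 3L) matrix(rgb, ncol = 3L) else as.matrix(rgb)
  od <- -log10(pmax(flat, 0.5) / i0)
  Vp <- solve(crossprod(V)) %*% t(V)   # pseudo-inverse
  dens <- od %*% t(Vp)
  dens[dens < 0] <- 0
  if (length(dims) == 3L) array(dens, c(dims[1], dims[2], ncol(V))) else dens
}
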