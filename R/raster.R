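# Rasters and affine transforms.
#
# Rasters are plain numeric matrices: rows are y (top to bottom), columns
# x, with a `pixel_size` (um/px) and `origin` (um of the top-left corner)
# attached as attributes. Pixel (i, j) covers the half-open cell
# [ox + (j-1)*px, ox + j*px) x [oy + (i-1)*px, oy + i*px) and is sampled at
# its centre.

#' Build an affine transform
#'
#' A 2x3 matrix mapping moving coordinates (um) into base coordinates:
#' `p' = A[,1:2] %*% p + A[,3]`, composed as
#' translation o rotation o scale o shear about `centre`.
#'
#' @param tx,ty translation in um.
#' @param theta rotation in radians.
#' @param sx,sy scale factors.
#' @param shear shear coefficient (x' = x + shear * y).
#' @param centre length-2 centre of rotation/scaling (um).
#' @return a 2x3 affine matrix.
#' @export
affine_transform <- function(tx = 0, ty = 0, theta = 0, sx = 1, sy = 1,
                             shear = 0, centre = c(0, 0)) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  S <- matrix(c(sx, 0, shear * sx, sy), 2)
  L <- R %*% S
  t0 <- c(tx, ty) + centre - L %*% centre
  cbind(L, t0)
}

#' Apply an affine transform to coordinates
#' @param A 2x3 affine matrix.
#' @param x,y coordinates, or `x` a ring/region with `y` missing.
#' @return transformed coordinates (matrix `cbind(x, y)`), or a
#'   ring/region if one was supplied.
#' @export
apply_affine <- function(A, x, y = NULL) {
  if (is.list(x)) {
    reg <- as_region(x)
    out <- lapply(reg, function(r) {
      m <- apply_affine(A, r$x, r$y)
      ring(m[, 1], m[, 2])
    })
    return(if (!is.null(x$x)) out[[1]] else out)
  }
  cbind(A[1, 1] * x + A[1, 2] * y + A[1, 3],
        A[2, 1] * x + A[2, 2] * y + A[2, 3])
}

#' Compose and invert affine transforms
#' @param A,B 2x3 affine matrices; the composition applies `B` first.
#' @return a 2x3 affine matrix.
#' @export
compose_affine <- function(A, B) {
  L <- A[, 1:2] %*% B[, 1:2]
  cbind(L, A[, 1:2] %*% B[, 3] + A[, 3])
}

#' @rdname compose_affine
#' @export
invert_affine <- function(A) {
  L <- A[, 1:2]
  d <- L[1, 1] * L[2, 2] - L[1, 2] * L[2, 1]
  if (abs(d) < 1e-12) stop("affine transform is not invertible")
  Li <- matrix(c(L[2, 2], -L[2, 1], -L[1, 2], L[1, 1]), 2) / d
  cbind(Li, -Li %*% A[, 3])
}

#' Rasterize a region onto a pixel grid
#'
#' Pixel-centre sampling: a pixel is set to `value` when its centre lies in
#' the region.
#'
#' @param reg region or ring (um coordinates).
#' @param bbox `c(xmin, ymin, xmax, ymax)` extent in um.
#' @param pixel_size um per pixel.
#' @param value value for covered pixels.
#' @param base optional existing raster to paint onto.
#' @param max_pixels guard against runaway grids.
#' @return a raster matrix with attributes `pixel_size` and `origin`.
#' @export
rasterize_region <- function(reg, bbox, pixel_size, value = 1,
                             base = NULL, max_pixels = 5e7) {
  nx <- ceiling((bbox[3] - bbox[1]) / pixel_size)
  ny <- ceiling((bbox[4] - bbox[2]) / pixel_size)
  if (nx * ny > max_pixels)
    stop("raster of ", nx, "x", ny, " pixels exceeds the pixel budget (",
         format(max_pixels, scientific = FALSE), ")")
  m <- if (is.null(base)) matrix(0, ny, nx) else base
  reg <- as_region(reg)
  for (r in reg) {
    j0 <- max(1L, floor((min(r$x) - bbox[1]) / pixel_size))
    j1 <- min(nx, ceiling((max(r$x) - bbox[1]) / pixel_size))
    i0 <- max(1L, floor((min(r$y) - bbox[2]) / pixel_size))
    i1 <- min(ny, ceiling((max(r$y) - bbox[2]) / pixel_size))
    if (j1 < j0 || i1 < i0) next
    jb <- j0:j1; ib <- i0:i1
    cx <- bbox[1] + (jb - 0.5) * pixel_size
    cy <- bbox[2] + (ib - 0.5) * pixel_size
    gx <- rep(cx, each = length(cy)); gy <- rep(cy, times = length(cx))
    inside <- sp::point.in.polygon(gx, gy, r$x, r$y) >= 1L
    sub <- m[ib, jb, drop = FALSE]
    # even-odd across rings: XOR holes out by toggling
    sub[matrix(inside, length(ib), length(jb))] <-
      ifelse(sub[matrix(inside, length(ib), length(jb))] == value, 0, value)
    m[ib, jb] <- sub
  }
  attr(m, "pixel_size") <- pixel_size
  attr(m, "origin") <- bbox[1:2]
  m
}

#' Render a synthetic section as per-stain rasters
#'
#' Rasterizes the planted stain polygons, each warped by its planted affine
#' misalignment, plus an unwarped base layer (the islet union, standing in
#' for the base CD45 image's tissue structure). The ProINS layer is
#' two-level: 1 for total, 2 inside the high-threshold region.
#'
#' @param section a [synth_section()] result.
#' @param pixel_size um per pixel, in `[0.2, 5]`.
#' @param misalignment named list of 2x3 affines (stain -> transform); a
#'   stain's raster shows its polygons mapped through the transform.
#' @param stains which stain layers to render.
#' @param max_pixels pixel budget guard.
#' @return list: `layers` (named raster matrices, including `base`),
#'   `pixel_size`, `bbox`, `affine_truth`.
#' @export
render_section <- function(section, pixel_size = 1, misalignment = list(),
                           stains = c("CHGA", "ProINS", "INS", "GCG", "SST", "PPY"),
                           max_pixels = 5e7) {
  if (pixel_size < 0.2 || pixel_size > 5)
    stop("pixel_size must be in [0.2, 5] um")
  bbox <- region_bbox(section$section$tissue)
  idm <- affine_transform()
  base <- rasterize_region(section$islets, bbox, pixel_size,
                           max_pixels = max_pixels)
  layers <- list(base = base)
  for (h in stains) {
    A <- misalignment[[h]]
    polys <- Filter(Negate(is.null), section$stains[[h]])
    if (!is.null(A)) polys <- lapply(polys, function(r) apply_affine(A, r))
    lay <- rasterize_region(polys, bbox, pixel_size, max_pixels = max_pixels)
    if (h == "ProINS") {
      hi <- Filter(Negate(is.null), section$stains[["ProINS_hi"]])
      if (!is.null(A)) hi <- lapply(hi, function(r) apply_affine(A, r))
      hi_m <- rasterize_region(hi, bbox, pixel_size, max_pixels = max_pixels)
      lay[hi_m > 0 & lay > 0] <- 2
    }
    layers[[h]] <- lay
  }
  aff <- stats::setNames(lapply(names(layers), function(h) {
    if (is.null(misalignment[[h]])) idm else misalignment[[h]]
  }), names(layers))
  list(layers = layers, pixel_size = pixel_size, bbox = bbox,
       affine_truth = aff)
}
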