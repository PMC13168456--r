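# Polygon primitives used throughout the pipeline.
#
# A "ring" is a list with numeric vectors `x` and `y` (an open vertex loop,
# last vertex not repeated), in micrometres, image convention (origin
# top-left, y increasing downward). A "region" is a list of rings; interior
# rings (holes) carry opposite orientation, as produced by polygon-clipping
# operations. All clipping goes through `poly_op()` so the snapping
# precision is set in exactly one place.

# vertex spacing used by the integer snapping of the clipping engine; in um
.CLIP_EPS <- 1e-9

#' Construct a polygon ring
#'
#' @param x,y numeric vertex coordinates in micrometres (open loop).
#' @return a ring: `list(x, y)`.
#' @export
ring <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3, all(is.finite(x)), all(is.finite(y)))
  list(x = as.numeric(x), y = as.numeric(y))
}

#' Signed area of a ring (shoelace)
#'
#' Positive for counter-clockwise vertex order in a standard mathematical
#' frame; with the image convention (y down) visual orientation is flipped,
#' which is irrelevant as long as use is consistent.
#' @param r a ring.
#' @return signed area in square micrometres.
#' @export
ring_signed_area <- function(r) {
  x <- r$x; y <- r$y
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

#' Area of a region
#'
#' Sum of signed ring areas, in absolute value, so holes subtract from
#' their enclosing ring.
#' @param reg a region (list of rings) or a single ring.
#' @return area in square micrometres.
#' @export
region_area <- function(reg) {
  reg <- as_region(reg)
  if (length(reg) == 0L) return(0)
  abs(sum(vapply(reg, ring_signed_area, numeric(1))))
}

#' Perimeter of a ring
#' @param r a ring.
#' @return perimeter in micrometres.
#' @export
ring_perimeter <- function(r) {
  x <- r$x; y <- r$y
  sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
}

#' Area centroid of a ring
#' @param r a ring.
#' @return numeric length-2 vector `c(x, y)`.
#' @export
ring_centroid <- function(r) {
  x <- r$x; y <- r$y
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(c(mean(x), mean(y)))
  c(sum((x + xs) * cr) / (6 * a), sum((y + ys) * cr) / (6 * a))
}

# normalize single ring vs region input
as_region <- function(p) {
  if (length(p) == 0L) return(list())
  if (!is.null(p$x)) list(p) else p
}

#' Polygon boolean operation
#'
#' Thin wrapper over the Vatti/Clipper engine with a fixed, fine snapping
#' grid so areas survive round-trips to well below 1e-6 um^2.
#' @param a,b regions (lists of rings) or single rings.
#' @param op one of "intersection", "union", "minus", "xor".
#' @return a region (possibly empty list).
#' @export
poly_op <- function(a, b, op = c("intersection", "union", "minus", "xor")) {
  op <- match.arg(op)
  a <- as_region(a); b <- as_region(b)
  if (length(a) == 0L) {
    if (op == "union") return(b)
    return(list())
  }
  if (length(b) == 0L) {
    if (op %in% c("union", "minus", "xor")) return(a)
    return(list())
  }
  polyclip::polyclip(a, b, op = op,
                     fillA = "nonzero", fillB = "nonzero",
                     x0 = 0, y0 = 0, eps = .CLIP_EPS)
}

#' Self-union of a set of rings
#'
#' Merges an arbitrary collection of (possibly overlapping or edge-sharing)
#' rings into a clean region.
#' @param rings list of rings.
#' @return a region.
#' @export
poly_union_all <- function(rings) {
  rings <- as_region(rings)
  if (length(rings) <= 1L) return(rings)
  polyclip::polyclip(rings, rings, op = "union",
                     fillA = "nonzero", fillB = "nonzero",
                     x0 = 0, y0 = 0, eps = .CLIP_EPS)
}

#' Offset (buffer) a region by a distance
#'
#' Positive `delta` grows, negative shrinks; joins are rounded.
#' @param reg a region or ring.
#' @param delta offset distance in micrometres.
#' @param arctol maximum deviation of the rounded-join approximation (um).
#' @return a region.
#' @export
poly_buffer <- function(reg, delta, arctol = abs(delta) / 100) {
  reg <- as_region(reg)
  if (length(reg) == 0L) return(list())
  polyclip::polyoffset(reg, delta, jointype = "round", arctol = arctol)
}

#' Point-in-region test (even-odd over rings)
#'
#' @param px,py point coordinates.
#' @param reg a region or ring.
#' @param boundary_inside treat points on a ring boundary as inside.
#' @return logical vector along `px`.
#' @export
pts_in_region <- function(px, py, reg, boundary_inside = TRUE) {
  reg <- as_region(reg)
  if (length(reg) == 0L) return(rep(FALSE, length(px)))
  inside <- integer(length(px))
  on_edge <- rep(FALSE, length(px))
  for (r in reg) {
    pip <- sp::point.in.polygon(px, py, r$x, r$y)
    inside <- inside + as.integer(pip == 1L)
    on_edge <- on_edge | pip >= 2L
  }
  ans <- (inside %% 2L) == 1L
  if (boundary_inside) ans | on_edge else ans & !on_edge
}

#' Minimum distance from points to the boundary of a region
#'
#' Distance to the nearest polygon edge (not vertex-only); zero only for
#' points exactly on the boundary. Combine with [pts_in_region()] for a
#' signed interpretation.
#' @param px,py point coordinates.
#' @param reg a region or ring.
#' @return numeric vector of distances in micrometres.
#' @export
dist_to_boundary <- function(px, py, reg) {
  reg <- as_region(reg)
  d <- rep(Inf, length(px))
  for (r in reg) d <- pmin(d, .dist_pts_segs(px, py, r$x, r$y))
  d
}

# point-to-closed-polyline distance, vectorized over points
.dist_pts_segs <- function(px, py, vx, vy) {
  x2 <- c(vx[-1], vx[1]); y2 <- c(vy[-1], vy[1])
  best <- rep(Inf, length(px))
  for (k in seq_along(vx)) {
    dx <- x2[k] - vx[k]; dy <- y2[k] - vy[k]
    len2 <- dx^2 + dy^2
    if (len2 == 0) {
      d2 <- (px - vx[k])^2 + (py - vy[k])^2
    } else {
      t <- pmin(1, pmax(0, ((px - vx[k]) * dx + (py - vy[k]) * dy) / len2))
      d2 <- (px - (vx[k] + t * dx))^2 + (py - (vy[k] + t * dy))^2
    }
    best <- pmin(best, d2)
  }
  sqrt(best)
}

#' Minimum distance between two polygon boundaries
#'
#' Evaluated vertex-to-edge in both directions; exact for the closest
#' approach of two polygons unless it falls strictly between vertices on
#' both, in which case it is a tight upper bound (vertex spacing sets the
#' tolerance).
#' @param a,b regions or rings.
#' @return distance in micrometres.
#' @export
poly_boundary_distance <- function(a, b) {
  a <- as_region(a); b <- as_region(b)
  d <- Inf
  for (ra in a) d <- min(d, min(dist_to_boundary(ra$x, ra$y, b)))
  for (rb in b) d <- min(d, min(dist_to_boundary(rb$x, rb$y, a)))
  d
}

#' Regular polygon approximation of a disc
#' @param cx,cy centre in micrometres.
#' @param r radius in micrometres.
#' @param n number of segments (default 128, the documented disc tolerance:
#'   area deficit of the inscribed 128-gon is ~0.1 percent).
#' @return a ring.
#' @export
disc_poly <- function(cx, cy, r, n = 128L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  ring(cx + r * cos(th), cy + r * sin(th))
}

#' Rectangle ring
#' @param xmin,ymin,xmax,ymax bounds in micrometres.
#' @return a ring.
#' @export
rect_poly <- function(xmin, ymin, xmax, ymax) {
  ring(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}

#' Scale a ring about a fixed point
#' @param r a ring.
#' @param s scale factor.
#' @param cx,cy fixed point; defaults to the ring centroid.
#' @return a ring.
#' @export
scale_ring <- function(r, s, cx = NULL, cy = NULL) {
  if (is.null(cx)) { ct <- ring_centroid(r); cx <- ct[1]; cy <- ct[2] }
  ring(cx + s * (r$x - cx), cy + s * (r$y - cy))
}

#' Bounding box of a region
#' @param reg region or ring.
#' @return `c(xmin, ymin, xmax, ymax)`.
#' @export
region_bbox <- function(reg) {
  reg <- as_region(reg)
  xs <- unlist(lapply(reg, `[[`, "x")); ys <- unlist(lapply(reg, `[[`, "y"))
  c(min(xs), min(ys), max(xs), max(ys))
}

# Second central moments of a simple polygon (per unit area), via Green's
# theorem. Returns covariance matrix entries of the uniform density on the
# polygon interior.
.poly_covariance <- function(r) {
  x <- r$x; y <- r$y
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  cx <- sum((x + xs) * cr) / (6 * a)
  cy <- sum((y + ys) * cr) / (6 * a)
  # raw second moments about the origin
  sxx <- sum((x^2 + x * xs + xs^2) * cr) / 12
  syy <- sum((y^2 + y * ys + ys^2) * cr) / 12
  sxy <- sum((x * ys + 2 * x * y + 2 * xs * ys + xs * y) * cr) / 24
  vxx <- sxx / a - cx^2
  vyy <- syy / a - cy^2
  vxy <- sxy / a - cx * cy
  list(vxx = vxx, vyy = vyy, vxy = vxy, cx = cx, cy = cy, area = abs(a))
}

#' Shape descriptors of a simple polygon
#'
#' Dimensionless descriptors in (0, 1]: aspect ratio (minor/major axis of
#' the ellipse with matching second central moments), solidity (area over
#' convex-hull area) and circularity (`4*pi*A/P^2`, capped at 1); plus the
#' equivalent circular diameter `d = 2*sqrt(A/pi)` and the volume of the
#' sphere of that diameter.
#'
#' @param r a ring (simple polygon, positive area).
#' @return named list: `area`, `perimeter`, `centroid_x`, `centroid_y`,
#'   `major_axis`, `minor_axis`, `aspect_ratio`, `solidity`, `circularity`,
#'   `equiv_diameter`, `sphere_volume`.
#' @export
compute_shape <- function(r) {
  a <- abs(ring_signed_area(r))
  if (a <= 0) stop("degenerate polygon: zero area")
  p <- ring_perimeter(r)
  m <- .poly_covariance(r)
  tr <- m$vxx + m$vyy
  det <- m$vxx * m$vyy - m$vxy^2
  disc <- sqrt(max(0, (tr / 2)^2 - det))
  l1 <- tr / 2 + disc; l2 <- max(0, tr / 2 - disc)
  major <- 4 * sqrt(l1); minor <- 4 * sqrt(l2)
  aspect <- if (major <= 0 || disc < 1e-12 * tr) 1 else minor / major
  hull <- grDevices::chull(r$x, r$y)
  hull_a <- abs(ring_signed_area(list(x = r$x[hull], y = r$y[hull])))
  solidity <- min(1, a / hull_a)
  circ <- min(1, 4 * pi * a / p^2)
  d <- 2 * sqrt(a / pi)
  list(area = a, perimeter = p, centroid_x = m$cx, centroid_y = m$cy,
       major_axis = major, minor_axis = minor, aspect_ratio = aspect,
       solidity = solidity, circularity = circ, equiv_diameter = d,
       sphere_volume = pi / 6 * d^3)
}

#' Split a region's rings into filled components (holes dropped)
#'
#' Rings enclosed by an odd number of other rings are interior holes;
#' dropping them "fills" each connected component, the convention used when
#' merging stain areas into contiguous islet objects.
#' @param reg a region.
#' @return list of rings, one filled outer boundary per component.
#' @export
fill_holes <- function(reg) {
  reg <- as_region(reg)
  if (length(reg) <= 1L) return(reg)
  n <- length(reg)
  depth <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      # ring i inside ring j? test one vertex (rings never cross post-clip)
      if (sp::point.in.polygon(reg[[i]]$x[1], reg[[i]]$y[1],
                               reg[[j]]$x, reg[[j]]$y) == 1L)
        depth[i] <- depth[i] + 1L
    }
  }
  reg[depth %% 2L == 0L]
}
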