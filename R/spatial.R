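# Boundary-aware spatial statistics over islet centroids.
#
# The modified Ripley statistic counts, for each islet and radius, the
# other islets within the disc, weights the count by the fraction of the
# disc lying inside the tissue boundary, averages over islets, and
# normalizes by the count expected under a uniform density (so complete
# spatial randomness gives K = 1 at every radius). The fractal dimension
# is the log-log slope of the boundary-adjusted count over radii > 600 um.

#' Default Ripley radii
#'
#' Log-spaced radii spanning the analysis range 400-10,000 um.
#' @param r_min,r_max radius range in um.
#' @param n number of radii.
#' @return numeric vector of radii.
#' @export
ripley_radii <- function(r_min = 400, r_max = 10000, n = 25L) {
  exp(seq(log(r_min), log(r_max), length.out = n))
}

#' Boundary-weighted modified Ripley's K
#'
#' For each islet `i` and radius `r`: `c_i(r)` is the cumulative count of
#' other islets within `r`; `w_i(r)` the fraction of the disc of radius
#' `r` centred on islet `i` lying inside the parenchyma (exact
#' circle-polygon intersection with a 128-segment disc); the
#' boundary-adjusted count is the mean of `c_i / w_i`; and
#' `K(r) = adjusted count / (lambda * pi * r^2)` with `lambda` the overall
#' islet density in the parenchyma. The area under the curve is
#' trapezoidal on (log r, K).
#'
#' @param x,y islet centroid coordinates, um.
#' @param parenchyma region (or `tissue_section`) bounding the tissue.
#' @param radii radii in um (default [ripley_radii()]).
#' @param disc_segments polygonal disc resolution.
#' @return object of class `ripley_curve`: `curve` (data.frame `radius`,
#'   `mean_count`, `adj_count`, `K`), `auc`, `lambda`, `n`.
#' @export
ripley_modified <- function(x, y, parenchyma, radii = ripley_radii(),
                            disc_segments = 128L) {
  if (length(x) < 2L) stop("need at least 2 centroids")
  par_reg <- if (inherits(parenchyma, "tissue_section")) parenchyma$parenchyma else as_region(parenchyma)
  A <- region_area(par_reg)
  if (A <= 0) stop("parenchyma area must be > 0")
  n <- length(x)
  lambda <- n / A
  D <- as.matrix(stats::dist(cbind(x, y)))
  srt <- apply(D, 2L, sort)           # columns: sorted distances per point
  dbound <- dist_to_boundary(x, y, par_reg)
  radii <- sort(radii)
  mean_count <- adj_count <- K <- numeric(length(radii))
  for (k in seq_along(radii)) {
    r <- radii[k]
    cnt <- vapply(seq_len(n), function(i)
      findInterval(r, srt[, i]) - 1L, numeric(1))
    w <- rep(1, n)
    needs <- which(dbound < r)
    for (i in needs) {
      disc <- disc_poly(x[i], y[i], r, disc_segments)
      w[i] <- region_area(poly_op(disc, par_reg, "intersection")) /
        abs(ring_signed_area(disc))
    }
    mean_count[k] <- mean(cnt)
    adj_count[k] <- mean(cnt / w)
    K[k] <- adj_count[k] / (lambda * pi * r^2)
  }
  lr <- log(radii)
  auc <- sum(diff(lr) * (K[-1] + K[-length(K)]) / 2)
  structure(list(curve = data.frame(radius = radii, mean_count = mean_count,
                                    adj_count = adj_count, K = K),
                 auc = auc, lambda = lambda, n = n, parenchyma_area = A),
            class = "ripley_curve")
}

#' @export
print.ripley_curve <- function(x, ...) {
  cat("<ripley_curve> n = ", x$n, ", mean K = ",
      signif(mean(x$curve$K), 4), ", AUC = ", signif(x$auc, 4), "\n", sep = "")
  invisible(x)
}

#' Fractal dimension from a Ripley curve
#'
#' Ordinary least-squares slope of log(boundary-adjusted count) against
#' log(radius), excluding radii at or below `min_radius` (600 um) and
#' non-positive counts. A uniform planar pattern gives slope 2; points on
#' a line give slope 1.
#'
#' @param ripley a [ripley_modified()] result.
#' @param min_radius radii at or below this are excluded, um.
#' @return the slope (fractal dimension), a single number.
#' @export
fractal_dimension <- function(ripley, min_radius = 600) {
  cv <- ripley$curve
  use <- cv$radius > min_radius & cv$adj_count > 0
  if (sum(use) < 3L)
    stop("fewer than 3 usable radii above ", min_radius, " um")
  unname(stats::coef(stats::lm(log(adj_count) ~ log(radius),
                               data = cv[use, ]))[2])
}

# triangulation edges/triangles; handles n < 3 and collinear degeneracy
.triangulate <- function(x, y) {
  n <- length(x)
  if (n == 2L) {
    return(list(edges = data.frame(ind1 = 1L, ind2 = 2L,
                                   length = sqrt(diff(x)^2 + diff(y)^2)),
                triangles = list()))
  }
  dd <- tryCatch(deldir::deldir(x, y, suppressMsge = TRUE),
                 error = function(e) NULL)
  if (is.null(dd) || nrow(dd$delsgs) == 0L) {
    warning("degenerate (collinear/duplicate) centroids: jittering by 1e-6 um")
    set.seed(0L)
    dd <- deldir::deldir(x + stats::runif(n, -1e-6, 1e-6),
                         y + stats::runif(n, -1e-6, 1e-6),
                         suppressMsge = TRUE)
  }
  sg <- dd$delsgs
  edges <- data.frame(ind1 = sg$ind1, ind2 = sg$ind2,
                      length = sqrt((sg$x1 - sg$x2)^2 + (sg$y1 - sg$y2)^2))
  tl <- deldir::triang.list(dd)
  triangles <- lapply(tl, function(t) {
    list(ind = t$ptNum,
         sides = sqrt((t$x - t$x[c(2, 3, 1)])^2 + (t$y - t$y[c(2, 3, 1)])^2),
         area = abs(ring_signed_area(list(x = t$x, y = t$y))))
  })
  list(edges = edges, triangles = triangles)
}

#' Delaunay neighborhood metrics
#'
#' Delaunay triangulation of the islet centroids; per islet, incident
#' edges longer than `max_radius` are discarded, the mean retained edge
#' length is the mean Delaunay distance, and the mean area of incident
#' triangles whose three sides are all retained is the mean Delaunay
#' area. An islet with no retained edge (no neighbor within the search
#' radius) falls back to distance `max_radius` and area
#' `pi * max_radius^2` (for the default 4 mm radius: pi x 16 mm^2).
#'
#' @param x,y centroid coordinates, um.
#' @param max_radius maximum search radius, um (default 4000).
#' @return data.frame: `islet_id`, `mean_delaunay_distance`,
#'   `mean_delaunay_area`, `neighbor_count`, `fallback`.
#' @export
delaunay_metrics <- function(x, y, max_radius = 4000) {
  n <- length(x)
  if (n < 1L) stop("need at least 1 centroid")
  fb_area <- pi * max_radius^2
  out <- data.frame(islet_id = seq_len(n),
                    mean_delaunay_distance = rep(max_radius, n),
                    mean_delaunay_area = rep(fb_area, n),
                    neighbor_count = 0L, fallback = TRUE)
  if (n == 1L) return(out)
  tg <- .triangulate(x, y)
  ed <- tg$edges[tg$edges$length <= max_radius, , drop = FALSE]
  if (nrow(ed)) {
    inc <- c(split(ed$length, factor(ed$ind1, levels = seq_len(n))),
             split(ed$length, factor(ed$ind2, levels = seq_len(n))))
    for (i in seq_len(n)) {
      lens <- c(inc[[i]], inc[[n + i]])
      if (length(lens)) {
        out$mean_delaunay_distance[i] <- mean(lens)
        out$neighbor_count[i] <- length(lens)
        out$fallback[i] <- FALSE
      }
    }
  }
  tri_ok <- Filter(function(t) all(t$sides <= max_radius), tg$triangles)
  if (length(tri_ok)) {
    sums <- numeric(n); cnts <- integer(n)
    for (t in tri_ok) {
      sums[t$ind] <- sums[t$ind] + t$area
      cnts[t$ind] <- cnts[t$ind] + 1L
    }
    has <- cnts > 0L
    out$mean_delaunay_area[has] <- sums[has] / cnts[has]
  }
  out
}

#' Class-specific Delaunay metrics and isolated-islet fractions
#'
#' Triangulation is run separately per class (e.g. UMAP cluster). An islet
#' is "isolated" when fewer than 2 same-class islets lie within
#' `max_radius` (8 mm), making triangulation-based neighborhood metrics
#' impossible for it; isolated islets carry NA metrics. Classes with fewer
#' than `min_class_n` (3) islets are excluded (reported missing).
#'
#' @param x,y centroid coordinates, um.
#' @param class class label per centroid.
#' @param max_radius search radius, um (default 8000).
#' @param min_class_n minimum islets for a class to be evaluated.
#' @return list: `per_islet` (islet_id, class, isolated, metrics),
#'   `per_class` (class, n, isolated_fraction, mean non-isolated Delaunay
#'   distance/area; NA rows for excluded classes).
#' @export
class_delaunay <- function(x, y, class, max_radius = 8000, min_class_n = 3L) {
  stopifnot(length(class) == length(x))
  cls <- sort(unique(as.character(class)))
  per_islet <- data.frame(islet_id = seq_along(x), class = as.character(class),
                          isolated = NA, mean_delaunay_distance = NA_real_,
                          mean_delaunay_area = NA_real_)
  per_class <- list()
  for (cl in cls) {
    idx <- which(as.character(class) == cl)
    if (length(idx) < min_class_n) {
      per_class[[cl]] <- data.frame(class = cl, n = length(idx),
                                    isolated_fraction = NA_real_,
                                    mean_delaunay_distance = NA_real_,
                                    mean_delaunay_area = NA_real_)
      next
    }
    D <- as.matrix(stats::dist(cbind(x[idx], y[idx])))
    n_within <- rowSums(D <= max_radius) - 1L
    iso <- n_within < 2L
    per_islet$isolated[idx] <- iso
    dm <- delaunay_metrics(x[idx], y[idx], max_radius = max_radius)
    ni <- !iso
    per_islet$mean_delaunay_distance[idx[ni]] <- dm$mean_delaunay_distance[ni]
    per_islet$mean_delaunay_area[idx[ni]] <- dm$mean_delaunay_area[ni]
    per_class[[cl]] <- data.frame(
      class = cl, n = length(idx), isolated_fraction = mean(iso),
      mean_delaunay_distance = if (any(ni)) mean(dm$mean_delaunay_distance[ni]) else NA_real_,
      mean_delaunay_area = if (any(ni)) mean(dm$mean_delaunay_area[ni]) else NA_real_)
  }
  list(per_islet = per_islet, per_class = do.call(rbind, per_class))
}

#' Back-project islet values onto the section outline
#'
#' Renders the tissue outline populated with islets at their original
#' locations as circles (radius proportional to sqrt(islet area), times a
#' global enlargement factor), colored either by categorical cluster or by
#' a 0-15+ capped CD45 burden scale.
#'
#' @param x,y centroids, um; @param area islet areas, um^2.
#' @param value per-islet value: factor/character for cluster coloring, or
#'   numeric CD45 counts (capped at `cd45_cap`).
#' @param section a `tissue_section` (outline); optional.
#' @param enlarge global circle enlargement factor.
#' @param cd45_cap top bin for the numeric scale (default 15, "15+").
#' @return a ggplot object.
#' @export
back_projection <- function(x, y, area, value = NULL, section = NULL,
                            enlarge = 2, cd45_cap = 15) {
  df <- data.frame(x = x, y = y, r = enlarge * sqrt(area / pi))
  p <- ggplot2::ggplot()
  if (!is.null(section)) {
    for (rg in as_region(section$tissue)) {
      out <- data.frame(x = c(rg$x, rg$x[1]), y = c(rg$y, rg$y[1]))
      p <- p + ggplot2::geom_path(data = out, ggplot2::aes(x = .data$x, y = .data$y),
                                  color = "grey40")
    }
  }
  if (nrow(df)) {
    if (is.null(value)) {
      p <- p + ggplot2::geom_point(data = df,
                                   ggplot2::aes(x = .data$x, y = .data$y,
                                                size = .data$r),
                                   shape = 21, fill = "grey70")
    } else if (is.numeric(value)) {
      df$v <- pmin(value, cd45_cap)
      lab <- paste0("associated CD45 (0-", cd45_cap, "+)")
      p <- p + ggplot2::geom_point(data = df,
                                   ggplot2::aes(x = .data$x, y = .data$y,
                                                size = .data$r, fill = .data$v),
                                   shape = 21) +
        ggplot2::scale_fill_gradient(low = "lightyellow", high = "red3",
                                     limits = c(0, cd45_cap), name = lab)
    } else {
      df$v <- factor(value)
      p <- p + ggplot2::geom_point(data = df,
                                   ggplot2::aes(x = .data$x, y = .data$y,
                                                size = .data$r, fill = .data$v),
                                   shape = 21) +
        ggplot2::labs(fill = "cluster")
    }
    p <- p + ggplot2::scale_size_identity()
  }
  p + ggplot2::scale_y_reverse() + ggplot2::coord_fixed() +
    ggplot2::theme_void() + ggplot2::labs(title = if (!is.null(section)) section$section_id else NULL)
}
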