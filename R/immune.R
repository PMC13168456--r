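# Peri-islet regions, CD45/nucleus attribution, and insulitis scoring.
#
# The peri-islet region is the 20 um band outside the islet boundary.
# Where bands of neighboring islets would overlap they are split along the
# locus equidistant to the two islet polygons (the continuous analogue of
# the raster watershed): each band is intersected with its islet's
# generalized Voronoi cell, approximated by the Voronoi diagram of densely
# sampled boundary points. Point attribution itself is exact (distance to
# polygon), independent of that polygon approximation.

# union-find for grouping islets with touching candidate bands
.uf_find <- function(parent, i) {
  while (parent[i] != i) { parent[i] <- parent[parent[i]]; i <- parent[i] }
  i
}

# resample a ring boundary at approximately `spacing` um
.sample_boundary <- function(r, spacing = 2) {
  x <- c(r$x, r$x[1]); y <- c(r$y, r$y[1])
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  s <- c(0, cumsum(seg))
  tt <- seq(0, s[length(s)], by = spacing)
  xi <- stats::approx(s, x, xout = tt)$y
  yi <- stats::approx(s, y, xout = tt)$y
  cbind(xi, yi)
}

#' Build non-overlapping peri-islet regions
#'
#' Each region is `(islet buffered by peri_width) minus islet`, clipped to
#' the tissue polygon, and -- where neighboring bands meet -- split along
#' the equidistant locus so that bands never overlap and every band point
#' is nearer to its own islet than to any other.
#'
#' @param islets list of islet rings (non-overlapping).
#' @param section a `tissue_section`, or NULL to skip tissue clipping.
#' @param peri_width band width in um (default 20).
#' @param boundary_spacing sampling step (um) of the equidistant-locus
#'   approximation; sets its tolerance.
#' @return object of class `peri_regions`: `regions` (list of regions) and
#'   `table` (data.frame islet_id, area).
#' @export
build_peri_regions <- function(islets, section = NULL, peri_width = 20,
                               boundary_spacing = 2) {
  n <- length(islets)
  if (n == 0L)
    return(structure(list(regions = list(),
                          table = data.frame(islet_id = integer(0),
                                             area = numeric(0))),
                     class = "peri_regions"))
  bbs <- t(vapply(islets, region_bbox, numeric(4)))
  # reject overlapping input islets
  for (i in seq_len(n)) {
    cand <- which(seq_len(n) > i &
                    bbs[, 1] <= bbs[i, 3] & bbs[, 3] >= bbs[i, 1] &
                    bbs[, 2] <= bbs[i, 4] & bbs[, 4] >= bbs[i, 2])
    for (j in cand) {
      if (region_area(poly_op(islets[[i]], islets[[j]], "intersection")) > 1e-6)
        stop("input islets ", i, " and ", j, " overlap")
    }
  }
  cands <- vector("list", n)
  for (i in seq_len(n)) {
    band <- poly_op(poly_buffer(islets[[i]], peri_width, arctol = 0.02),
                    islets[[i]], "minus")
    if (!is.null(section)) band <- poly_op(band, section$tissue, "intersection")
    cands[[i]] <- band
  }
  # group islets whose candidate bands intersect
  parent <- seq_len(n)
  ebb <- bbs + matrix(c(-peri_width, -peri_width, peri_width, peri_width),
                      nrow(bbs), 4L, byrow = TRUE)
  for (i in seq_len(n)) {
    cand <- which(seq_len(n) > i &
                    ebb[, 1] <= ebb[i, 3] & ebb[, 3] >= ebb[i, 1] &
                    ebb[, 2] <= ebb[i, 4] & ebb[, 4] >= ebb[i, 2])
    for (j in cand) {
      if (region_area(poly_op(cands[[i]], cands[[j]], "intersection")) > 1e-9) {
        ri <- .uf_find(parent, i); rj <- .uf_find(parent, j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), function(i) .uf_find(parent, i), integer(1))
  out <- cands
  for (g in unique(roots)) {
    members <- which(roots == g)
    if (length(members) < 2L) next
    samp <- lapply(members, function(i)
      do.call(rbind, lapply(as_region(islets[[i]]),
                            .sample_boundary, spacing = boundary_spacing)))
    np <- vapply(samp, nrow, integer(1))
    all_s <- do.call(rbind, samp)
    owner <- rep(members, np)
    rw <- c(min(all_s[, 1]), max(all_s[, 1]), min(all_s[, 2]), max(all_s[, 2])) +
      c(-1, 1, -1, 1) * (peri_width + 10)
    # regular boundary samples are near-degenerate (cocircular) for the
    # Voronoi construction; apply a deterministic jitter, escalating its
    # amplitude (still far below the boundary-sampling tolerance) until
    # the triangulation succeeds
    ii <- seq_len(nrow(all_s))
    hash <- sin(ii * rep_len(c(12.9898, 78.233), length(ii)))
    dd <- NULL
    for (amp in c(0.01, 0.3, 1)) {
      utils::capture.output(utils::capture.output(dd <- tryCatch(
        deldir::deldir(all_s[, 1] + amp * hash, all_s[, 2] + amp * rev(hash),
                       rw = rw, suppressMsge = TRUE),
        error = function(e) NULL), type = "message"))
      if (!is.null(dd)) break
    }
    if (is.null(dd))
      stop("Voronoi partition of peri-islet bands failed for islet group ",
           paste(members, collapse = ", "))
    tiles <- deldir::tile.list(dd)
    for (i in members) {
      mine <- which(owner[dd$ind.orig] == i)
      cell <- poly_union_all(lapply(tiles[mine], function(t) ring(t$x, t$y)))
      out[[i]] <- poly_op(cands[[i]], cell, "intersection")
    }
  }
  areas <- vapply(out, region_area, numeric(1))
  structure(list(regions = out,
                 table = data.frame(islet_id = seq_len(n), area = areas)),
            class = "peri_regions")
}

#' @export
print.peri_regions <- function(x, ...) {
  cat("<peri_regions> ", nrow(x$table), " bands, total area ",
      signif(sum(x$table$area), 6), " um^2\n", sep = "")
  invisible(x)
}

# grid-bucketed candidate lookup: which points fall near each islet bbox
.bucket_points <- function(px, py, cell) {
  key <- paste(floor(px / cell), floor(py / cell))
  split(seq_along(px), key)
}
.cells_for_bbox <- function(bb, cell) {
  jx <- floor(bb[1] / cell):floor(bb[3] / cell)
  jy <- floor(bb[2] / cell):floor(bb[4] / cell)
  as.vector(outer(jx, jy, paste))
}

#' Attribute CD45 and nucleus centroids to islet compartments
#'
#' Each point is assigned to exactly one compartment: `intra` (inside an
#' islet polygon, boundary inclusive), `peri` (outside all islets, within
#' `peri_width` of the nearest islet boundary -- nearest-islet attribution,
#' ties to the lower islet id -- and inside the tissue), or unassigned.
#' Frequencies are CD45 per 100 nuclei; densities are counts per mm^2 of
#' compartment area.
#'
#' @param cd45,nuclei data.frames with `x`, `y` columns (um, base frame).
#' @param islets list of islet rings.
#' @param peri_regions a [build_peri_regions()] result (supplies band
#'   areas for densities); rebuilt when NULL.
#' @param section optional `tissue_section` (peri points must lie in
#'   tissue).
#' @param peri_width band width in um.
#' @return object of class `immune_profiles`: `profiles` (per-islet
#'   data.frame) and `assignment` (per-point islet/compartment for both
#'   point sets).
#' @export
assign_cells <- function(cd45, nuclei, islets, peri_regions = NULL,
                         section = NULL, peri_width = 20) {
  n <- length(islets)
  if (is.null(peri_regions))
    peri_regions <- build_peri_regions(islets, section, peri_width)
  assign_one_set <- function(pts) {
    m <- nrow(pts)
    islet_of <- integer(m); comp <- rep("none", m)
    if (m == 0L || n == 0L)
      return(data.frame(islet_id = islet_of, compartment = comp))
    cell <- max(200, 2 * peri_width)
    buckets <- .bucket_points(pts$x, pts$y, cell)
    best_d <- rep(Inf, m)
    for (i in seq_len(n)) {
      bb <- region_bbox(islets[[i]]) +
        c(-peri_width, -peri_width, peri_width, peri_width) +
        c(-cell, -cell, cell, cell)
      idx <- unlist(buckets[.cells_for_bbox(bb, cell)], use.names = FALSE)
      if (!length(idx)) next
      px <- pts$x[idx]; py <- pts$y[idx]
      inside <- pts_in_region(px, py, islets[[i]], boundary_inside = TRUE)
      if (any(inside)) {
        ii <- idx[inside]
        islet_of[ii] <- i; comp[ii] <- "intra"; best_d[ii] <- -1
      }
      rest <- !inside
      if (any(rest)) {
        d <- dist_to_boundary(px[rest], py[rest], islets[[i]])
        cand <- d <= peri_width + 1e-9
        if (any(cand)) {
          ii <- idx[rest][cand]; dd <- d[cand]
          upd <- dd < best_d[ii] - 1e-12 & comp[ii] != "intra"
          ii <- ii[upd]; dd <- dd[upd]
          islet_of[ii] <- i; comp[ii] <- "peri"; best_d[ii] <- dd
        }
      }
    }
    if (!is.null(section) && any(comp == "peri")) {
      per <- which(comp == "peri")
      ok <- pts_in_region(pts$x[per], pts$y[per], section$tissue,
                          boundary_inside = TRUE)
      islet_of[per[!ok]] <- 0L; comp[per[!ok]] <- "none"
    }
    data.frame(islet_id = islet_of, compartment = comp)
  }
  a_cd45 <- assign_one_set(cd45)
  a_nuc <- assign_one_set(nuclei)
  cnt <- function(a, cmp) {
    tab <- table(factor(a$islet_id[a$compartment == cmp], levels = seq_len(n)))
    as.integer(tab)
  }
  islet_areas <- vapply(islets, region_area, numeric(1))
  prof <- data.frame(
    islet_id = seq_len(n),
    intra_cd45 = cnt(a_cd45, "intra"), peri_cd45 = cnt(a_cd45, "peri"),
    intra_nuclei = cnt(a_nuc, "intra"), peri_nuclei = cnt(a_nuc, "peri"),
    islet_area = islet_areas,
    peri_area = peri_regions$table$area)
  prof$intra_freq <- ifelse(prof$intra_nuclei > 0,
                            100 * prof$intra_cd45 / prof$intra_nuclei, NA_real_)
  prof$peri_freq <- ifelse(prof$peri_nuclei > 0,
                           100 * prof$peri_cd45 / prof$peri_nuclei, NA_real_)
  prof$intra_density <- prof$intra_cd45 / (prof$islet_area / 1e6)
  prof$peri_density <- ifelse(prof$peri_area > 0,
                              prof$peri_cd45 / (prof$peri_area / 1e6), NA_real_)
  prof$total_associated <- prof$intra_cd45 + prof$peri_cd45
  prof$any_cd45 <- prof$total_associated >= 1L
  prof <- flag_insulitis(prof)
  structure(list(profiles = prof,
                 assignment = list(cd45 = a_cd45, nuclei = a_nuc)),
            class = "immune_profiles")
}

#' Flag insulitic islets
#'
#' An islet is insulitic when its total associated (intra- plus
#' peri-islet) CD45+ count reaches the consensus threshold of 15 cells;
#' 14 cells is not insulitic.
#'
#' @param profiles per-islet data.frame with `intra_cd45`, `peri_cd45` (or
#'   `total_associated`).
#' @param threshold minimum associated CD45+ cells (default 15).
#' @return `profiles` with columns `total_associated` and `insulitic`.
#' @export
flag_insulitis <- function(profiles, threshold = 15L) {
  if (is.null(profiles$total_associated))
    profiles$total_associated <- profiles$intra_cd45 + profiles$peri_cd45
  profiles$insulitic <- profiles$total_associated >= threshold
  profiles
}

#' Donor-level insulitis diagnosis
#'
#' A donor is diagnosed with insulitis when at least `min_islets` (3)
#' insulitic islets are found, by default pooled across all of the donor's
#' sections and regions; `per_section = TRUE` requires the islets within a
#' single section.
#'
#' @param profiles per-islet data.frame with `donor_id`, `section_id`,
#'   `insulitic` (see [flag_insulitis()]).
#' @param min_islets minimum insulitic islets for a positive call.
#' @param per_section require the supporting islets in one section.
#' @return data.frame: `donor_id`, `n_insulitic`, `insulitis` (logical),
#'   `supporting_islets` (comma-separated section:islet ids).
#' @export
diagnose_insulitis <- function(profiles, min_islets = 3L,
                               per_section = FALSE) {
  stopifnot(!is.null(profiles$donor_id), !is.null(profiles$insulitic))
  donors <- sort(unique(profiles$donor_id))
  rows <- lapply(donors, function(d) {
    p <- profiles[profiles$donor_id == d & profiles$insulitic, , drop = FALSE]
    if (per_section && nrow(p)) {
      per <- table(p$section_id)
      pos <- any(per >= min_islets)
      nmax <- if (length(per)) max(per) else 0L
      n_rep <- as.integer(nmax)
    } else {
      pos <- nrow(p) >= min_islets
      n_rep <- nrow(p)
    }
    data.frame(donor_id = d, n_insulitic = n_rep, insulitis = pos,
               supporting_islets = paste(p$section_id, p$islet_id,
                                         sep = ":", collapse = ","))
  })
  do.call(rbind, rows)
}

#' Donor-level CD45 burden metrics
#'
#' Per donor: the fraction of islets with at least one associated CD45+
#' cell, mean intra-/peri-islet CD45 frequencies and their ratio, total
#' associated CD45+ cells, and the associated CD45+ density over the
#' summed islet plus peri-islet area.
#'
#' @param profiles per-islet data.frame with `donor_id` and the columns of
#'   [assign_cells()] output.
#' @return data.frame, one row per donor.
#' @export
cohort_cd45_metrics <- function(profiles) {
  stopifnot(!is.null(profiles$donor_id), nrow(profiles) >= 1L)
  donors <- sort(unique(profiles$donor_id))
  rows <- lapply(donors, function(d) {
    p <- profiles[profiles$donor_id == d, , drop = FALSE]
    assoc_area <- sum(p$islet_area) + sum(p$peri_area)
    data.frame(
      donor_id = d,
      n_islets = nrow(p),
      frac_islets_ge1_cd45 = mean(p$total_associated >= 1),
      mean_intra_freq = mean(p$intra_freq, na.rm = TRUE),
      mean_peri_freq = mean(p$peri_freq, na.rm = TRUE),
      peri_intra_freq_ratio = {
        mi <- mean(p$intra_freq, na.rm = TRUE)
        if (is.finite(mi) && mi > 0) mean(p$peri_freq, na.rm = TRUE) / mi else NA_real_
      },
      total_associated_cd45 = sum(p$total_associated),
      associated_cd45_density_mm2 = sum(p$total_associated) / (assoc_area / 1e6),
      n_insulitic = sum(p$insulitic))
  })
  do.call(rbind, rows)
}
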