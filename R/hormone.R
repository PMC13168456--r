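# Per-islet hormone staining quantification: areas, fractions, pairwise
# overlap (Jaccard) statistics, deficiency phenotypes, and section-level
# endocrine summaries. All measurement is exact polygon arithmetic; raster
# inputs are vectorized once by `segment_stain_regions()` (where the
# intensity thresholds, including the two-level ProINS hi/total pair,
# apply) and measured here as polygons.

#' Canonical hormone panel
#'
#' The eight hormone stains quantified per islet; `ProINS_hi` is the
#' high-threshold subset of `ProINS`.
#' @export
HORMONES <- c("CHGA", "ProINS", "INS", "IAPP", "ProGCG", "GCG", "SST", "PPY")

# clip a flat stain region to one islet, with bbox prefilter
.clip_to_islet <- function(stain, islet, islet_bb) {
  stain <- as_region(stain)
  if (length(stain) == 0L) return(list())
  keep <- vapply(stain, function(r) {
    !(max(r$x) < islet_bb[1] || min(r$x) > islet_bb[3] ||
        max(r$y) < islet_bb[2] || min(r$y) > islet_bb[4])
  }, logical(1))
  if (!any(keep)) return(list())
  poly_op(stain[keep], islet, "intersection")
}

#' Measure per-islet hormone staining areas
#'
#' Clips each hormone's stain geometry to the islet polygon and records
#' absolute areas and fractions of islet area, the union endocrine area,
#' and (optionally) all pairwise intersection/union areas for overlap
#' statistics.
#'
#' @param islet a ring (islet polygon, base frame).
#' @param stains named list: hormone -> region (rings) in the base frame;
#'   may include `ProINS_hi`. Missing hormones are measured as zero.
#' @param islet_id identifier copied into the output.
#' @param pairwise also compute the 28 unordered pairwise
#'   intersection/union areas over the 8-hormone panel (the full ordered
#'   set is recovered by symmetry).
#' @return list of class `hormone_profile`: `row` (one-row data.frame) and
#'   `pairs` (long data.frame of pairwise areas, or NULL).
#' @export
measure_hormone_areas <- function(islet, stains, islet_id = 1L,
                                  pairwise = TRUE) {
  a_islet <- region_area(islet)
  if (a_islet <= 0) stop("islet polygon has zero area")
  bb <- region_bbox(islet)
  clipped <- lapply(stains, .clip_to_islet, islet = islet, islet_bb = bb)
  area_of <- function(h) if (is.null(clipped[[h]])) 0 else region_area(clipped[[h]])
  areas <- vapply(HORMONES, area_of, numeric(1))
  hi <- area_of("ProINS_hi")
  if (hi > areas[["ProINS"]] + 1e-6)
    stop("ProINS_hi area exceeds total ProINS area: inconsistent thresholds")
  endo <- poly_union_all(unlist(lapply(HORMONES, function(h) clipped[[h]]),
                                recursive = FALSE))
  endo_area <- region_area(endo)
  row <- data.frame(islet_id = islet_id, islet_area = a_islet,
                    endocrine_union_area = endo_area,
                    proins_hi_area = hi,
                    proins_hi_frac = hi / a_islet)
  for (h in HORMONES) {
    row[[paste0("area_", h)]] <- areas[[h]]
    row[[paste0("frac_", h)]] <- areas[[h]] / a_islet
  }
  row$ins_gcg_ratio <- if (areas[["GCG"]] > 0) areas[["INS"]] / areas[["GCG"]] else NA_real_
  pairs <- NULL
  if (pairwise) {
    cmb <- utils::combn(HORMONES, 2)
    inter <- numeric(ncol(cmb)); uni <- numeric(ncol(cmb))
    for (k in seq_len(ncol(cmb))) {
      A <- clipped[[cmb[1, k]]]; B <- clipped[[cmb[2, k]]]
      aA <- if (is.null(A)) 0 else region_area(A)
      aB <- if (is.null(B)) 0 else region_area(B)
      if (aA == 0 || aB == 0) {
        inter[k] <- 0; uni[k] <- aA + aB
      } else {
        ia <- region_area(poly_op(A, B, "intersection"))
        inter[k] <- ia
        uni[k] <- aA + aB - ia
      }
    }
    pairs <- data.frame(islet_id = islet_id,
                        h1 = cmb[1, ], h2 = cmb[2, ],
                        intersection = inter, union = uni)
  }
  structure(list(row = row, pairs = pairs), class = "hormone_profile")
}

#' Pairwise Jaccard index matrix
#'
#' `J(a, b) = |a n b| / |a u b|` over the 8-hormone panel; symmetric with
#' unit diagonal where the stain is present; `NA` where the union is empty.
#'
#' @param profile a `hormone_profile` (from [measure_hormone_areas()] with
#'   `pairwise = TRUE`) or its `pairs` data.frame.
#' @return 8x8 symmetric numeric matrix.
#' @export
jaccard_matrix <- function(profile) {
  pairs <- if (inherits(profile, "hormone_profile")) profile$pairs else profile
  if (is.null(pairs)) stop("pairwise areas missing; rerun with pairwise = TRUE")
  if (any(pairs$intersection < -1e-9) || any(pairs$union < -1e-9))
    stop("negative overlap areas: corrupt input")
  J <- matrix(NA_real_, length(HORMONES), length(HORMONES),
              dimnames = list(HORMONES, HORMONES))
  for (k in seq_len(nrow(pairs))) {
    v <- if (pairs$union[k] > 0) pairs$intersection[k] / pairs$union[k] else NA_real_
    J[pairs$h1[k], pairs$h2[k]] <- v
    J[pairs$h2[k], pairs$h1[k]] <- v
  }
  # diagonal: defined (=1) only for present stains
  row <- if (inherits(profile, "hormone_profile")) profile$row else NULL
  for (h in HORMONES) {
    present <- if (!is.null(row)) row[[paste0("area_", h)]] > 0 else {
      any(pairs$union[pairs$h1 == h | pairs$h2 == h] > 0)
    }
    J[h, h] <- if (isTRUE(present)) 1 else NA_real_
  }
  J
}

#' Classify hormone-deficiency phenotypes
#'
#' A hormone is deficient when its staining area is `< 1%` of islet area;
#' positive when `>= 1%` (exactly 1% is positive). The insulin-deficient
#' islet (IDI) call defaults to the ProINS-based definition; the INS-based
#' variant is always emitted alongside and can be promoted via
#' `idi_definition`.
#'
#' @param profiles data.frame of per-islet rows (the `row` parts of
#'   [measure_hormone_areas()], rbind-ed), with `frac_<hormone>` columns.
#' @param threshold deficiency boundary as a fraction (default 0.01).
#' @param idi_definition `"ProINS"` (default) or `"INS"`.
#' @return the input with logical columns `deficient_<h>` and
#'   `positive_<h>` per hormone, plus `idi_proins`, `idi_ins`, `idi`,
#'   `gcg_deficient`, `ppy_pos`, `sst_pos`.
#' @export
classify_deficiency <- function(profiles, threshold = 0.01,
                                idi_definition = c("ProINS", "INS")) {
  idi_definition <- match.arg(idi_definition)
  for (h in HORMONES) {
    f <- profiles[[paste0("frac_", h)]]
    profiles[[paste0("deficient_", h)]] <- f < threshold
    profiles[[paste0("positive_", h)]] <- f >= threshold
  }
  profiles$idi_proins <- profiles$deficient_ProINS
  profiles$idi_ins <- profiles$deficient_INS
  profiles$idi <- if (idi_definition == "ProINS") profiles$idi_proins else profiles$idi_ins
  profiles$gcg_deficient <- profiles$deficient_GCG
  profiles$ppy_pos <- profiles$positive_PPY
  profiles$sst_pos <- profiles$positive_SST
  profiles
}

#' Section-level endocrine summary
#'
#' Cumulative per-hormone and islet area fractions of the parenchyma (or
#' total tissue), islet density, and -- when a regional pancreas weight is
#' supplied -- islet and endocrine cell-type mass
#' (`mass = fraction x regional weight`).
#'
#' @param section a `tissue_section`.
#' @param profiles per-islet profile data.frame (`islet_area`,
#'   `area_<hormone>` columns).
#' @param regional_weight_g regional pancreas weight in grams (NA: mass
#'   fields are reported missing, fractions still computed).
#' @param denominator `"parenchyma"` (default) or `"tissue"`.
#' @return one-row data.frame: `n_islets`, `islet_density_mm2`,
#'   `islet_area_fraction`, `islet_mass_g`, and per hormone
#'   `fraction_<h>` / `mass_<h>_g`.
#' @export
section_summary <- function(section, profiles, regional_weight_g = NA_real_,
                            denominator = c("parenchyma", "tissue")) {
  denominator <- match.arg(denominator)
  denom_area <- region_area(section[[denominator]])
  if (denom_area <= 0) stop("denominator area must be > 0")
  if (is.na(regional_weight_g))
    warning("regional pancreas weight missing: mass fields reported as NA")
  n <- nrow(profiles)
  out <- data.frame(section_id = section$section_id,
                    n_islets = n,
                    islet_density_mm2 = n / (denom_area / 1e6),
                    islet_area_fraction = sum(profiles$islet_area) / denom_area)
  out$islet_mass_g <- out$islet_area_fraction * regional_weight_g
  for (h in HORMONES) {
    f <- sum(profiles[[paste0("area_", h)]]) / denom_area
    out[[paste0("fraction_", h)]] <- f
    out[[paste0("mass_", h, "_g")]] <- f * regional_weight_g
  }
  out
}

#' Fit a one-phase association curve
#'
#' Least-squares fit of `y = plateau + span * exp(-k * x)` with data-driven
#' starts; `span` may take either sign.
#'
#' @param x,y numeric vectors (e.g. islet areas and a per-islet property).
#' @return list: `plateau`, `span`, `k`, `r_squared`, `fitted`; or `NULL`
#'   when the fit does not converge.
#' @export
fit_one_phase <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L || stats::sd(y) == 0) return(NULL)
  o <- order(x)
  y_lo <- mean(y[o][seq_len(max(3L, length(x) %/% 10))])
  y_hi <- mean(y[rev(o)][seq_len(max(3L, length(x) %/% 10))])
  st <- list(plateau = y_hi, span = y_lo - y_hi, k = 1 / mean(x))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ plateau + span * exp(-k * x), start = st,
                      lower = c(-Inf, -Inf, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  co <- stats::coef(fit)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(plateau = unname(co["plateau"]), span = unname(co["span"]),
       k = unname(co["k"]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
       fitted = stats::fitted(fit))
}

#' Size-binned property curves with a one-phase association fit
#'
#' Stratifies islets into `n_bins` equal-width bins of log2(area), reports
#' per-bin means with 95% confidence intervals (bins with fewer than
#' `min_islets` islets are reported missing), and fits
#' `y = plateau + span * exp(-k * A)` on the islet-level data.
#'
#' @param areas islet areas, um^2.
#' @param values per-islet property values.
#' @param n_bins number of log2-area bins (default 14).
#' @param min_islets minimum islets for a bin to be reported (default 3).
#' @return list of class `size_binned_curve`: `bins` (data.frame:
#'   `bin`, `log2_area_mid`, `area_mid`, `n`, `mean`, `ci_lo`, `ci_hi`) and
#'   `fit` (see [fit_one_phase()]; NULL when unavailable).
#' @export
size_binned_curves <- function(areas, values, n_bins = 14L, min_islets = 3L) {
  if (length(areas) < 3L) stop("need at least 3 islets")
  la <- log2(areas)
  brk <- seq(min(la), max(la), length.out = n_bins + 1L)
  brk[length(brk)] <- brk[length(brk)] + 1e-9
  bin <- findInterval(la, brk, rightmost.closed = TRUE)
  bin[bin > n_bins] <- n_bins
  rows <- lapply(seq_len(n_bins), function(b) {
    v <- values[bin == b]
    n <- sum(is.finite(v))
    mid <- (brk[b] + brk[b + 1]) / 2
    if (n < min_islets)
      return(data.frame(bin = b, log2_area_mid = mid, area_mid = 2^mid,
                        n = n, mean = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_))
    m <- mean(v, na.rm = TRUE)
    se <- stats::sd(v, na.rm = TRUE) / sqrt(n)
    ci <- stats::qt(0.975, n - 1) * se
    data.frame(bin = b, log2_area_mid = mid, area_mid = 2^mid, n = n,
               mean = m, ci_lo = m - ci, ci_hi = m + ci)
  })
  structure(list(bins = do.call(rbind, rows),
                 fit = fit_one_phase(areas, values)),
            class = "size_binned_curve")
}
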