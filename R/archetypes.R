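# Donor archetypes: parameter bundles that drive the synthetic cohort
# generator. Defaults ship as an annotated YAML config; every field can be
# overridden per call.

.archetype_cache <- new.env(parent = emptyenv())

.load_archetype_config <- function() {
  if (is.null(.archetype_cache$cfg)) {
    path <- system.file("extdata", "archetypes.yaml", package = "isletscape")
    if (path == "") path <- file.path("inst", "extdata", "archetypes.yaml")
    .archetype_cache$cfg <- yaml::read_yaml(path)
  }
  .archetype_cache$cfg
}

#' Donor groups and pancreas regions
#' @export
DONOR_GROUPS <- c("Ctrl", "AAb", "T1DS", "T1DL")

#' @rdname DONOR_GROUPS
#' @export
PANCREAS_REGIONS <- c("PT", "PH")

# resolve a possibly region-keyed scalar
.by_region <- function(v, region) {
  if (is.list(v)) v[[region]] else v
}

#' Build a donor archetype
#'
#' Resolves the shipped defaults for a donor group and pancreas region into
#' a flat parameter bundle, optionally overriding individual fields.
#'
#' @param group donor group, one of `"Ctrl"`, `"AAb"`, `"T1DS"`, `"T1DL"`.
#' @param region pancreas region, `"PT"` (tail) or `"PH"` (head).
#' @param override named list of fields to replace (post-resolution names,
#'   e.g. `idi_fraction = 0.5` or `islet_density = 3`).
#' @return an object of class `donor_archetype`.
#' @examples
#' a <- donor_archetype("Ctrl", "PT")
#' a$idi_fraction
#' @export
donor_archetype <- function(group = DONOR_GROUPS, region = PANCREAS_REGIONS,
                            override = list()) {
  group <- match.arg(group)
  region <- match.arg(region)
  cfg <- .load_archetype_config()
  g <- cfg$groups[[group]]
  a <- cfg$common
  a$group <- group
  a$region <- region
  a$islet_density <- g$islet_density
  for (f in c("idi_fraction", "gcg_deficient_small_fraction",
              "ppy_uncinate_fraction", "insulitic_islet_fraction",
              "p_gamma_given_idi")) {
    a[[f]] <- .by_region(g[[f]], region)
  }
  a$high_burden_fraction_ici <- g$high_burden_fraction_ici
  a$p_residual_given_alpha_idi <- g$p_residual_given_alpha_idi
  if (length(override)) {
    stopifnot(!is.null(names(override)), all(nzchar(names(override))))
    a[names(override)] <- override
  }
  validate_archetype(a)
  structure(a, class = "donor_archetype")
}

#' Validate archetype invariants
#'
#' Checks fraction bounds, positive density and distribution parameters.
#' @param a an archetype (list).
#' @return the archetype, invisibly; errors on violation.
#' @export
validate_archetype <- function(a) {
  fr <- c("idi_fraction", "gcg_deficient_small_fraction",
          "ppy_uncinate_fraction", "insulitic_islet_fraction",
          "high_burden_fraction_ici", "p_gamma_given_idi",
          "p_residual_given_alpha_idi")
  for (f in fr) {
    v <- a[[f]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop("archetype field '", f, "' must be a fraction in [0, 1]")
  }
  if (!is.numeric(a$islet_density) || a$islet_density <= 0)
    stop("islet_density must be > 0")
  if (!is.numeric(a$size_log_sd) || a$size_log_sd < 0)
    stop("size_log_sd must be >= 0")
  if (!is.numeric(a$shape_noise) || a$shape_noise < 0 || a$shape_noise > 0.35)
    stop("shape_noise must be in [0, 0.35] to keep islets star-shaped")
  invisible(a)
}

#' @export
print.donor_archetype <- function(x, ...) {
  cat("<donor_archetype> ", x$group, " / ", x$region, "\n", sep = "")
  cat("  islet density:   ", x$islet_density, " / mm^2\n", sep = "")
  cat("  size lognormal:  meanlog ", signif(x$size_log_mean, 5),
      ", sdlog ", signif(x$size_log_sd, 5), "\n", sep = "")
  cat("  IDI fraction:    ", x$idi_fraction, "\n", sep = "")
  cat("  insulitic frac:  ", x$insulitic_islet_fraction, "\n", sep = "")
  invisible(x)
}
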