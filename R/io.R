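# Readers and writers: GeoJSON geometry (um coordinates), point CSVs,
# TIFF rasters with a JSON sidecar, donor metadata, and run manifests.

.ring_to_geojson_coords <- function(r) {
  lapply(c(seq_along(r$x), 1L), function(i) c(r$x[i], r$y[i]))
}

.region_to_geojson <- function(reg) {
  reg <- as_region(reg)
  list(type = "Polygon",
       coordinates = lapply(reg, .ring_to_geojson_coords))
}

.geojson_to_region <- function(geom) {
  if (geom$type == "Polygon") {
    lapply(geom$coordinates, function(cc) {
      m <- do.call(rbind, lapply(cc, unlist))
      # drop the closing vertex
      if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
      ring(m[, 1], m[, 2])
    })
  } else if (geom$type == "MultiPolygon") {
    unlist(lapply(geom$coordinates, function(pc) {
      lapply(pc, function(cc) {
        m <- do.call(rbind, lapply(cc, unlist))
        if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
        ring(m[, 1], m[, 2])
      })
    }), recursive = FALSE)
  } else {
    stop("unsupported GeoJSON geometry type: ", geom$type)
  }
}

#' Write section geometry as GeoJSON
#'
#' One FeatureCollection holding the tissue and parenchyma outlines, the
#' islet polygons (with any table columns as properties), and optionally
#' the per-stain regions. Coordinates are micrometres in the base frame.
#'
#' @param section a `tissue_section`.
#' @param file output path.
#' @param islets optional list of islet rings.
#' @param islet_table optional data.frame of per-islet properties
#'   (row-aligned with `islets`).
#' @param stains optional named list: hormone -> list of rings.
#' @return `file`, invisibly.
#' @export
write_section_geojson <- function(section, file, islets = NULL,
                                  islet_table = NULL, stains = NULL) {
  feats <- list(
    list(type = "Feature", properties = list(role = "tissue"),
         geometry = .region_to_geojson(section$tissue)),
    list(type = "Feature", properties = list(role = "parenchyma"),
         geometry = .region_to_geojson(section$parenchyma)))
  for (i in seq_along(islets)) {
    props <- list(role = "islet", islet_id = i)
    if (!is.null(islet_table)) props <- c(props, as.list(islet_table[i, ]))
    feats[[length(feats) + 1L]] <-
      list(type = "Feature", properties = props,
           geometry = .region_to_geojson(islets[[i]]))
  }
  for (h in names(stains)) {
    for (i in seq_along(stains[[h]])) {
      r <- stains[[h]][[i]]
      if (is.null(r)) next
      feats[[length(feats) + 1L]] <-
        list(type = "Feature",
             properties = list(role = "stain", hormone = h, islet_id = i),
             geometry = .region_to_geojson(r))
    }
  }
  obj <- list(type = "FeatureCollection",
              properties = list(section_id = section$section_id,
                                donor_id = section$donor_id,
                                group = section$group,
                                region = section$region),
              features = feats)
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read section geometry from GeoJSON
#'
#' Inverse of [write_section_geojson()]; also accepts generic
#' FeatureCollections whose features carry a `role` property of `tissue`,
#' `parenchyma`, `islet` or `stain`.
#'
#' @param file GeoJSON path.
#' @return list: `section` (tissue_section), `islets`, `stains`.
#' @export
read_section_geojson <- function(file) {
  obj <- jsonlite::read_json(file)
  roles <- vapply(obj$features, function(f)
    as.character(f$properties$role %||% "unknown"), character(1))
  pick <- function(role) {
    idx <- which(roles == role)
    unlist(lapply(idx, function(i) .geojson_to_region(obj$features[[i]]$geometry)),
           recursive = FALSE)
  }
  tis <- pick("tissue"); par <- pick("parenchyma")
  if (length(par) == 0L) par <- tis
  meta <- obj$properties
  sec <- tissue_section(meta$section_id %||% basename(file),
                        meta$donor_id %||% basename(file),
                        meta$group %||% "Ctrl", meta$region %||% "PT",
                        tissue = tis, parenchyma = par)
  iidx <- which(roles == "islet")
  islets <- lapply(iidx, function(i) .geojson_to_region(obj$features[[i]]$geometry)[[1]])
  sidx <- which(roles == "stain")
  stains <- list()
  for (i in sidx) {
    h <- obj$features[[i]]$properties$hormone
    stains[[h]] <- c(stains[[h]], .geojson_to_region(obj$features[[i]]$geometry))
  }
  list(section = sec, islets = islets, stains = stains)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read centroid points CSV
#'
#' Columns `x_um`, `y_um`, `kind` (`cd45` or `nucleus`).
#' @param points data.frame with `x`, `y`, `kind`.
#' @param file path.
#' @return the file (write) or a data.frame with `x`, `y`, `kind` (read).
#' @export
write_points_csv <- function(points, file) {
  utils::write.csv(data.frame(x_um = points$x, y_um = points$y,
                              kind = points$kind),
                   file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_points_csv
#' @export
read_points_csv <- function(file) {
  df <- utils::read.csv(file)
  need <- c("x_um", "y_um", "kind")
  if (!all(need %in% names(df)))
    stop("points CSV must have columns ", paste(need, collapse = ", "))
  bad <- setdiff(unique(df$kind), c("cd45", "nucleus"))
  if (length(bad)) stop("unknown point kind(s): ", paste(bad, collapse = ", "))
  data.frame(x = df$x_um, y = df$y_um, kind = df$kind)
}

#' Write a raster as 8-bit TIFF with a JSON sidecar
#'
#' The sidecar (`<file>.json`) records pixel size, origin and the stain
#' name, which [read_raster_tiff()] restores as attributes.
#'
#' @param raster matrix with `pixel_size`/`origin` attributes.
#' @param file output TIFF path.
#' @param stain stain name recorded in the sidecar.
#' @param max_value intensity mapped to 255.
#' @return `file`, invisibly.
#' @export
write_raster_tiff <- function(raster, file, stain = NA_character_,
                              max_value = max(raster, 1)) {
  tiff::writeTIFF(pmin(raster / max_value, 1), file, bits.per.sample = 8L)
  meta <- list(pixel_size_um = attr(raster, "pixel_size"),
               origin_um = attr(raster, "origin") %||% c(0, 0),
               stain = stain, max_value = max_value)
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' @rdname write_raster_tiff
#' @export
read_raster_tiff <- function(file) {
  m <- tiff::readTIFF(file)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  sidecar <- paste0(file, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    m <- m * (meta$max_value %||% 1)
    attr(m, "pixel_size") <- meta$pixel_size_um
    attr(m, "origin") <- unlist(meta$origin_um)
    attr(m, "stain") <- meta$stain
  }
  m
}

#' Read donor metadata CSV
#'
#' Expected columns: `donor_id`, `group` (Ctrl/AAb/T1DS/T1DL); optional
#' `age`, `sex`, `bmi`, `autoantibody_count`, `t1d_duration`,
#' `weight_pt_g`, `weight_ph_g`, `hla_class2_bin`
#' (high/moderate/neutral/protective/unknown).
#'
#' @param file CSV path.
#' @return validated data.frame with an `hla_risk_score` column appended.
#' @export
read_donor_metadata <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("donor_id", "group") %in% names(df)))
    stop("donor metadata must have donor_id and group columns")
  bad <- setdiff(unique(df$group), DONOR_GROUPS)
  if (length(bad)) stop("unknown donor group(s): ", paste(bad, collapse = ", "))
  for (w in c("weight_pt_g", "weight_ph_g")) {
    if (!is.null(df[[w]]) && any(df[[w]] < 0, na.rm = TRUE))
      stop("negative pancreas weight in column ", w)
  }
  if (!is.null(df$hla_class2_bin)) {
    df$hla_risk_score <- hla_risk_score(df$hla_class2_bin)
  }
  df
}

#' Write a run manifest
#'
#' JSON manifest with the configuration hash, seeds, package version and a
#' digest of every output file.
#'
#' @param dir run directory.
#' @param config the configuration list.
#' @param seed master seed.
#' @return path of the manifest, invisibly.
#' @export
write_run_manifest <- function(dir, config, seed) {
  files <- sort(setdiff(list.files(dir, recursive = TRUE),
                        "manifest.json"))
  digests <- vapply(files, function(f)
    digest::digest(file.path(dir, f), file = TRUE), character(1))
  man <- list(config_hash = digest::digest(config),
              seed = seed,
              package_version = as.character(utils::packageVersion("isletscape")),
              files = as.list(digests))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
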