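# Pipeline orchestration: configuration, per-section analysis, cohort
# assembly, donor-level metrics and report tables. All randomness derives
# from the single seed in the configuration, so reruns with the same
# configuration are byte-identical.

#' HLA class II risk-bin score
#'
#' Numerical values for the DR-DQ risk bins: high +2, moderate +1,
#' neutral 0, protective -1; unknown is missing (absence is not
#' neutrality).
#'
#' @param bin character vector of bins.
#' @return integer vector (NA for unknown).
#' @export
hla_risk_score <- function(bin) {
  map <- c(high = 2L, moderate = 1L, neutral = 0L, protective = -1L,
           unknown = NA_integer_)
  bin <- tolower(as.character(bin))
  bad <- setdiff(unique(bin[!is.na(bin)]), names(map))
  if (length(bad)) stop("unrecognized HLA risk bin(s): ",
                        paste(bad, collapse = ", "))
  unname(map[bin])
}

#' Default pipeline configuration
#'
#' A fully populated configuration for a synthetic demonstration cohort.
#' Every analysis parameter the pipeline uses is reachable here.
#'
#' @param seed master seed.
#' @param donors_per_group synthetic donors per donor group.
#' @param width_mm,height_mm section dimensions.
#' @param n_islets optional per-section islet count override.
#' @return a nested configuration list (class `isletscape_config`).
#' @export
pipeline_config <- function(seed = 1L, donors_per_group = 2L,
                            width_mm = 12, height_mm = 12, n_islets = NULL) {
  structure(list(
    version = "1.0",
    seed = as.integer(seed),
    cohort = list(donors_per_group = as.integer(donors_per_group),
                  groups = DONOR_GROUPS,
                  regions = PANCREAS_REGIONS,
                  width_mm = width_mm, height_mm = height_mm,
                  n_islets = n_islets,
                  weights_g = list(PT = 30, PH = 40),
                  archetype_overrides = NULL),
    islets = list(min_area = 1000, border_distance = 10,
                  min_solidity = NULL),
    hormones = list(deficiency_threshold = 0.01,
                    idi_definition = "ProINS",
                    denominator = "parenchyma"),
    immune = list(peri_width = 20, insulitis_cells = 15L,
                  insulitis_islets = 3L, per_section = FALSE),
    spatial = list(ripley_r_min = 400, ripley_r_max = 10000,
                   ripley_n_radii = 25L, fractal_min_radius = 600,
                   delaunay_radius = 4000, class_delaunay_radius = 8000),
    clustering = list(n_neighbors = 50L, min_dist = 0.1, n_epochs = 1000L,
                      umap_seed = 0L, eps1 = 0.5, min_pts1 = 50L,
                      eps2 = 0.2, min_pts2 = 20L,
                      cd45_high = 5, cd45_residual = 1)),
    class = "isletscape_config")
}

#' Read / write a pipeline configuration
#' @param config a configuration list; @param file YAML path.
#' @return the configuration (read) or `file` (write).
#' @export
write_config <- function(config, file) {
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

#' @rdname write_config
#' @export
read_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  if (is.null(cfg$version)) stop("configuration lacks a version field")
  structure(cfg, class = "isletscape_config")
}

#' Match detected islets to generator ground truth
#'
#' Pairs each detected islet with the planted islet whose generation
#' centre it contains, and reports the intersection-over-union of the two
#' polygons.
#'
#' @param islet_set a [build_islet_objects()] result.
#' @param synth a [synth_section()] result.
#' @return data.frame: `islet_id` (detected), `truth_id` (planted, NA if
#'   unmatched), `iou`.
#' @export
match_islets_to_truth <- function(islet_set, synth) {
  tx <- synth$truth$x; ty <- synth$truth$y
  rows <- lapply(seq_along(islet_set$polygons), function(i) {
    p <- islet_set$polygons[[i]]
    bb <- region_bbox(p)
    cand <- which(tx >= bb[1] & tx <= bb[3] & ty >= bb[2] & ty <= bb[4])
    hit <- cand[pts_in_region(tx[cand], ty[cand], p)]
    if (length(hit) != 1L)
      return(data.frame(islet_id = i, truth_id = NA_integer_, iou = NA_real_))
    tp <- synth$islets[[hit]]
    inter <- region_area(poly_op(p, tp, "intersection"))
    uni <- region_area(p) + region_area(tp) - inter
    data.frame(islet_id = i, truth_id = hit, iou = inter / uni)
  })
  do.call(rbind, rows)
}

# bbox-index stains (flat per hormone) to detected islets
.stains_for_islet <- function(stain_bbs, stains_flat, islet_bb) {
  out <- list()
  for (h in names(stains_flat)) {
    bb <- stain_bbs[[h]]
    if (is.null(bb) || nrow(bb) == 0L) next
    keep <- which(bb[, 1] <= islet_bb[3] & bb[, 3] >= islet_bb[1] &
                    bb[, 2] <= islet_bb[4] & bb[, 4] >= islet_bb[2])
    if (length(keep)) out[[h]] <- stains_flat[[h]][keep]
  }
  out
}

#' Analyze one section
#'
#' The per-section stage chain: islet construction from stain geometry,
#' hormone quantification, peri-islet regions and immune attribution, and
#' per-section spatial statistics.
#'
#' @param section a `tissue_section`.
#' @param stains named list: hormone -> list of rings (base frame).
#' @param points data.frame `x`, `y`, `kind` (cd45/nucleus).
#' @param config a [pipeline_config()].
#' @param pairwise compute pairwise hormone overlaps per islet.
#' @return list: `islets` (islet_set), `profiles` (hormone + deficiency
#'   data.frame), `immune` (per-islet), `pairs` (pairwise overlap areas),
#'   `delaunay`, `ripley`, `fractal`, `summary`.
#' @export
analyze_section <- function(section, stains, points,
                            config = pipeline_config(), pairwise = TRUE) {
  ic <- config$islets
  det_stains <- stains[intersect(c("CHGA", "ProINS", "INS", "GCG", "SST", "PPY"),
                                 names(stains))]
  islets <- build_islet_objects(det_stains, section,
                                min_area = ic$min_area,
                                border_distance = ic$border_distance,
                                min_solidity = ic$min_solidity)
  n <- length(islets$polygons)
  stains_flat <- lapply(stains, function(s) Filter(Negate(is.null), s))
  stain_bbs <- lapply(stains_flat, function(s)
    if (length(s)) t(vapply(s, region_bbox, numeric(4))) else NULL)
  profs <- vector("list", n); pair_list <- vector("list", n)
  for (i in seq_len(n)) {
    p <- islets$polygons[[i]]
    hp <- measure_hormone_areas(p, .stains_for_islet(stain_bbs, stains_flat,
                                                     region_bbox(p)),
                                islet_id = i, pairwise = pairwise)
    profs[[i]] <- hp$row; pair_list[[i]] <- hp$pairs
  }
  profiles <- if (n) do.call(rbind, profs) else
    data.frame(islet_id = integer(0))
  if (n) profiles <- classify_deficiency(
    profiles, threshold = config$hormones$deficiency_threshold,
    idi_definition = config$hormones$idi_definition)
  peri <- build_peri_regions(islets$polygons, section,
                             peri_width = config$immune$peri_width)
  cd45 <- points[points$kind == "cd45", , drop = FALSE]
  nuc <- points[points$kind == "nucleus", , drop = FALSE]
  imm <- assign_cells(cd45, nuc, islets$polygons, peri, section,
                      peri_width = config$immune$peri_width)
  prof_imm <- flag_insulitis(imm$profiles,
                             threshold = config$immune$insulitis_cells)
  sp <- config$spatial
  del <- if (n >= 1L)
    delaunay_metrics(islets$table$centroid_x, islets$table$centroid_y,
                     max_radius = sp$delaunay_radius)
  else data.frame()
  rip <- if (n >= 2L)
    ripley_modified(islets$table$centroid_x, islets$table$centroid_y,
                    section,
                    radii = ripley_radii(sp$ripley_r_min, sp$ripley_r_max,
                                         sp$ripley_n_radii))
  else NULL
  frac <- if (!is.null(rip))
    tryCatch(fractal_dimension(rip, sp$fractal_min_radius),
             error = function(e) NA_real_)
  else NA_real_
  wt <- config$cohort$weights_g[[section$region]] %||% NA_real_
  summ <- if (n) section_summary(section, profiles, regional_weight_g = wt,
                                 denominator = config$hormones$denominator)
  else NULL
  list(islets = islets, profiles = profiles, immune = prof_imm,
       pairs = do.call(rbind, pair_list), peri = peri, delaunay = del,
       ripley = rip, fractal = frac, summary = summ,
       assignment = imm$assignment)
}

#' Run the full pipeline on a synthetic cohort
#'
#' Simulates the configured cohort (one section per donor, regions
#' alternating across donors within each group), analyzes every section,
#' clusters the pooled single-islet cohort, computes class-specific
#' Delaunay metrics per section, and writes all tables plus a manifest to
#' `outdir`.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created); `NULL` skips writing.
#' @param progress print per-stage progress lines.
#' @return list of class `isletscape_run`: `islet_table` (master per-islet
#'   table), `sections` (per-section results), `clustering`,
#'   `donor_metrics`, `insulitis`, `section_summaries`, `spatial_summary`,
#'   `truth` (pooled generator truth), `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL,
                         progress = interactive()) {
  co <- config$cohort
  say <- function(...) if (progress) message(...)
  sections <- list(); synths <- list()
  donor_meta <- list()
  k <- 0L
  for (g in co$groups) {
    for (d in seq_len(co$donors_per_group)) {
      k <- k + 1L
      region <- co$regions[[(d - 1L) %% length(co$regions) + 1L]]
      donor_id <- sprintf("%s_%02d", g, d)
      sec_seed <- (config$seed %% 100000L) * 10000L + k
      say("simulate ", donor_id, " (", region, "), seed ", sec_seed)
      arch <- donor_archetype(g, region,
                              override = co$archetype_overrides %||% list())
      sy <- synth_section(g, region, seed = sec_seed,
                          width_mm = co$width_mm, height_mm = co$height_mm,
                          n_islets = co$n_islets, archetype = arch,
                          section_id = paste0(donor_id, "_", region),
                          donor_id = donor_id)
      synths[[sy$section$section_id]] <- sy
      donor_meta[[donor_id]] <- data.frame(donor_id = donor_id, group = g,
                                           region = region)
    }
  }
  res <- list()
  for (sid in names(synths)) {
    say("analyze ", sid)
    sy <- synths[[sid]]
    pts <- sy$points[, c("x", "y", "kind")]
    res[[sid]] <- analyze_section(sy$section, sy$stains, pts, config)
  }
  # master per-islet table
  master <- do.call(rbind, lapply(names(res), function(sid) {
    r <- res[[sid]]
    n <- length(r$islets$polygons)
    if (!n) return(NULL)
    sy <- synths[[sid]]
    cbind(data.frame(section_id = sid,
                     donor_id = sy$section$donor_id,
                     group = sy$section$group,
                     region = sy$section$region),
          r$islets$table[, setdiff(names(r$islets$table), "islet_id")],
          r$profiles[, setdiff(names(r$profiles), "islet_id")],
          r$immune[, setdiff(names(r$immune), c("islet_id", "islet_area"))],
          data.frame(islet_id = r$islets$table$islet_id,
                     mean_delaunay_distance = r$delaunay$mean_delaunay_distance,
                     mean_delaunay_area = r$delaunay$mean_delaunay_area))
  }))
  say("cluster ", nrow(master), " islets")
  cc <- config$clustering
  Z <- assemble_features(master, master, master, master$circularity)
  emb <- embed_umap(Z, n_neighbors = cc$n_neighbors, min_dist = cc$min_dist,
                    n_epochs = cc$n_epochs, seed = cc$umap_seed)
  cl <- dbscan_two_rounds(emb, eps1 = cc$eps1, min_pts1 = cc$min_pts1,
                          eps2 = cc$eps2, min_pts2 = cc$min_pts2)
  ids <- sort(unique(cl$major[!is.na(cl$major)]))
  st <- do.call(rbind, lapply(ids, function(kk) {
    idx <- which(!is.na(cl$major) & cl$major == kk)
    data.frame(cluster = kk, n = length(idx),
               mean_frac_ProINS = mean(master$frac_ProINS[idx]),
               mean_frac_GCG = mean(master$frac_GCG[idx]),
               mean_frac_PPY = mean(master$frac_PPY[idx]),
               mean_frac_CHGA = mean(master$frac_CHGA[idx]),
               mean_cd45 = mean(master$total_associated[idx]))
  }))
  if (!is.null(st) && nrow(st))
    st <- label_clusters(st, cd45_high = cc$cd45_high,
                         cd45_residual = cc$cd45_residual)
  map <- if (!is.null(st) && nrow(st))
    stats::setNames(as.character(st$label), st$cluster) else character(0)
  master$cluster_major <- cl$major
  master$cluster_sub <- cl$sub
  master$cluster_label <- unname(map[as.character(cl$major)])
  master$key_cluster <- as.character(
    assign_cluster_key(master$frac_INS, master$frac_GCG,
                       master$total_associated, master$frac_PPY,
                       cd45_high = cc$cd45_high,
                       cd45_residual = cc$cd45_residual))
  master$umap_1 <- emb[, 1]; master$umap_2 <- emb[, 2]
  # class-specific Delaunay per section, classes = semantic labels
  say("class-specific Delaunay")
  cds <- lapply(names(res), function(sid) {
    rows <- which(master$section_id == sid & !is.na(master$cluster_label))
    if (length(rows) < 3L) return(NULL)
    cd <- class_delaunay(master$centroid_x[rows], master$centroid_y[rows],
                         master$cluster_label[rows],
                         max_radius = config$spatial$class_delaunay_radius)
    cbind(section_id = sid, cd$per_class)
  })
  class_del <- do.call(rbind, cds)
  master$isolated <- NA
  for (sid in names(res)) {
    rows <- which(master$section_id == sid & !is.na(master$cluster_label))
    if (length(rows) < 3L) next
    cd <- class_delaunay(master$centroid_x[rows], master$centroid_y[rows],
                         master$cluster_label[rows],
                         max_radius = config$spatial$class_delaunay_radius)
    master$isolated[rows] <- cd$per_islet$isolated
  }
  insl <- diagnose_insulitis(master, min_islets = config$immune$insulitis_islets,
                             per_section = config$immune$per_section)
  donor_met <- cohort_cd45_metrics(master)
  sect_sum <- do.call(rbind, lapply(res, `[[`, "summary"))
  spatial_sum <- do.call(rbind, lapply(names(res), function(sid) {
    r <- res[[sid]]
    data.frame(section_id = sid,
               ripley_auc = if (!is.null(r$ripley)) r$ripley$auc else NA_real_,
               ripley_mean_K = if (!is.null(r$ripley)) mean(r$ripley$curve$K) else NA_real_,
               fractal_dimension = r$fractal)
  }))
  truth <- do.call(rbind, lapply(names(synths), function(sid)
    cbind(section_id = sid, synths[[sid]]$truth)))
  run <- structure(list(islet_table = master, sections = res,
                        synthetic = synths,
                        cluster_stats = st, insulitis = insl,
                        donor_metrics = donor_met,
                        section_summaries = sect_sum,
                        spatial_summary = spatial_sum,
                        class_delaunay = class_del,
                        truth = truth, config = config),
                   class = "isletscape_run")
  if (!is.null(outdir)) {
    dir.create(file.path(outdir, "tables"), recursive = TRUE,
               showWarnings = FALSE)
    wr <- function(df, f) if (!is.null(df))
      utils::write.csv(df, file.path(outdir, "tables", f), row.names = FALSE)
    wr(master, "islet_master.csv")
    wr(insl, "insulitis_diagnosis.csv")
    wr(donor_met, "donor_cd45_metrics.csv")
    wr(sect_sum, "section_summaries.csv")
    wr(spatial_sum, "spatial_summary.csv")
    wr(class_del, "class_delaunay.csv")
    wr(if (!is.null(st)) st else NULL, "cluster_stats.csv")
    wr(truth, "truth.csv")
    dir.create(file.path(outdir, "sections"), showWarnings = FALSE)
    for (sid in names(synths)) {
      sy <- synths[[sid]]
      write_section_geojson(sy$section,
                            file.path(outdir, "sections",
                                      paste0(sid, ".geojson")),
                            islets = res[[sid]]$islets$polygons,
                            islet_table = res[[sid]]$islets$table)
      write_points_csv(sy$points,
                       file.path(outdir, "sections", paste0(sid, "_points.csv")))
    }
    write_config(config, file.path(outdir, "config.yaml"))
    write_run_manifest(outdir, config, config$seed)
  }
  run
}

#' @export
print.isletscape_run <- function(x, ...) {
  cat("<isletscape_run> ", nrow(x$islet_table), " islets across ",
      length(x$sections), " sections\n", sep = "")
  invisible(x)
}

#' Cohort report tables
#'
#' Descriptive summaries over a completed run: donor means of the
#' deficiency phenotypes, cluster magnitude table (fraction of islets per
#' cluster, by group), insulitis diagnoses, immune burden metrics, and the
#' per-section spatial summary. Per-cluster values are suppressed when
#' supported by fewer than 3 islets or fewer than 2 donors.
#'
#' @param run an `isletscape_run` (or a run directory containing
#'   `tables/islet_master.csv`).
#' @return list of data.frames: `donor_phenotypes`, `group_means`,
#'   `cluster_magnitude`, `insulitis`, `immune`, `spatial`.
#' @export
cohort_report <- function(run) {
  if (is.character(run)) {
    f <- file.path(run, "tables", "islet_master.csv")
    if (!file.exists(f)) stop("not a run directory: ", run)
    master <- utils::read.csv(f)
    spatial <- tryCatch(utils::read.csv(file.path(run, "tables", "spatial_summary.csv")),
                        error = function(e) NULL)
    insl <- tryCatch(utils::read.csv(file.path(run, "tables", "insulitis_diagnosis.csv")),
                     error = function(e) NULL)
  } else {
    master <- run$islet_table; spatial <- run$spatial_summary
    insl <- run$insulitis
  }
  by_donor <- split(master, master$donor_id)
  donor_phen <- do.call(rbind, lapply(by_donor, function(p) {
    data.frame(donor_id = p$donor_id[1], group = p$group[1],
               region = p$region[1], n_islets = nrow(p),
               idi_fraction = mean(p$idi),
               gcg_deficient_fraction = mean(p$gcg_deficient),
               ppy_pos_fraction = mean(p$ppy_pos),
               sst_pos_fraction = mean(p$sst_pos),
               frac_ge1_cd45 = mean(p$total_associated >= 1),
               median_islet_area = stats::median(p$area))
  }))
  grp <- split(donor_phen, donor_phen$group)
  group_means <- do.call(rbind, lapply(grp, function(g) {
    data.frame(group = g$group[1], n_donors = nrow(g),
               idi_fraction = mean(g$idi_fraction),
               gcg_deficient_fraction = mean(g$gcg_deficient_fraction),
               ppy_pos_fraction = mean(g$ppy_pos_fraction),
               sst_pos_fraction = mean(g$sst_pos_fraction),
               frac_ge1_cd45 = mean(g$frac_ge1_cd45))
  }))
  lv <- !is.na(master$cluster_label)
  mag <- NULL
  if (any(lv)) {
    tab <- table(master$group[lv], master$cluster_label[lv])
    nd <- tapply(master$donor_id[lv],
                 list(master$group[lv], master$cluster_label[lv]),
                 function(d) length(unique(d)))
    frac <- prop.table(tab, 1)
    frac[tab < 3 | (!is.na(nd) & nd < 2)] <- NA  # suppression rule
    mag <- as.data.frame.matrix(frac)
    mag <- cbind(group = rownames(mag), mag)
    rownames(mag) <- NULL
  }
  list(donor_phenotypes = donor_phen[order(donor_phen$donor_id), ],
       group_means = group_means,
       cluster_magnitude = mag,
       insulitis = insl,
       immune = if (is.character(run)) NULL else run$donor_metrics,
       spatial = spatial)
}
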