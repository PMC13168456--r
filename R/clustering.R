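# Single-islet phenotyping: feature assembly, UMAP embedding, two-round
# DBSCAN, data-driven semantic labels (I, II, III, IV, V-A, V-BC), and the
# rule-based approximate key usable with a standard three-stain panel.

#' Assemble the single-islet feature matrix
#'
#' Columns (fixed order): natural-log (pseudo-count 1 um^2) of the eight
#' hormone stain areas, the union endocrine area, the islet area and the
#' mean Delaunay area; the islet-associated CD45+ count (raw); and
#' circularity. Every column is z-scored across the supplied cohort;
#' constant columns become zeros with a warning.
#'
#' @param profiles per-islet hormone profile data.frame (`islet_area`,
#'   `endocrine_union_area`, `area_<hormone>` columns).
#' @param immune per-islet immune data.frame (`total_associated`).
#' @param spatial per-islet Delaunay data.frame (`mean_delaunay_area`).
#' @param circularity per-islet circularity vector.
#' @return numeric matrix (islets x 13 features) with attribute `centers`
#'   and `scales` recording the z-score parameters.
#' @export
assemble_features <- function(profiles, immune, spatial, circularity) {
  n <- nrow(profiles)
  if (nrow(immune) != n || nrow(spatial) != n || length(circularity) != n)
    stop("per-islet inputs have mismatched row counts")
  logp <- function(v) log(v + 1)
  M <- cbind(
    sapply(HORMONES, function(h) logp(profiles[[paste0("area_", h)]])),
    log_endocrine_union = logp(profiles$endocrine_union_area),
    log_islet_area = logp(profiles$islet_area),
    log_delaunay_area = logp(spatial$mean_delaunay_area),
    cd45_count = immune$total_associated,
    circularity = circularity)
  colnames(M)[seq_along(HORMONES)] <- paste0("log_area_", HORMONES)
  if (anyNA(M)) stop("missing entries in the feature matrix")
  ctr <- colMeans(M)
  scl <- apply(M, 2, stats::sd)
  zero <- scl == 0
  if (any(zero)) {
    warning("constant feature column(s) ",
            paste(colnames(M)[zero], collapse = ", "), ": z-scores set to 0")
    scl[zero] <- 1
  }
  Z <- scale(M, center = ctr, scale = scl)
  attr(Z, "centers") <- ctr
  attr(Z, "scales") <- scl
  Z
}

#' UMAP embedding of the islet feature matrix
#'
#' Seeded, single-threaded (hence reproducible) UMAP with the pipeline's
#' standard parameters: `n_neighbors = 50`, `min_dist = 0.1`,
#' `n_epochs = 1000`.
#'
#' @param features numeric matrix (islets x features).
#' @param n_neighbors,min_dist,n_epochs UMAP parameters.
#' @param seed integer seed (default 0).
#' @return n x 2 embedding matrix with a `params` attribute.
#' @export
embed_umap <- function(features, n_neighbors = 50L, min_dist = 0.1,
                       n_epochs = 1000L, seed = 0L) {
  if (nrow(features) <= n_neighbors)
    stop("cohort of ", nrow(features), " islets is not larger than ",
         "n_neighbors = ", n_neighbors, "; reduce n_neighbors")
  emb <- uwot::umap(features, n_neighbors = n_neighbors, min_dist = min_dist,
                    n_epochs = n_epochs, seed = seed,
                    n_threads = 1L, n_sgd_threads = 1L, batch = FALSE)
  attr(emb, "params") <- list(n_neighbors = n_neighbors, min_dist = min_dist,
                              n_epochs = n_epochs, seed = seed)
  emb
}

#' Density-based clustering (DBSCAN)
#'
#' Classic DBSCAN on 2D points with a grid-accelerated radius search.
#' Points in no dense neighborhood are noise (label 0).
#'
#' @param X numeric matrix (n x 2).
#' @param eps neighborhood radius.
#' @param min_pts minimum neighborhood size (the point itself counts).
#' @return integer labels, 0 for noise.
#' @export
dbscan_cluster <- function(X, eps, min_pts) {
  n <- nrow(X)
  cx <- floor(X[, 1] / eps); cy <- floor(X[, 2] / eps)
  key <- paste(cx, cy)
  buckets <- split(seq_len(n), key)
  neigh <- function(i) {
    ks <- as.vector(outer(cx[i] + (-1:1), cy[i] + (-1:1), paste))
    cand <- unlist(buckets[ks], use.names = FALSE)
    cand[(X[cand, 1] - X[i, 1])^2 + (X[cand, 2] - X[i, 2])^2 <= eps^2]
  }
  labels <- integer(n)       # 0 = noise/unclaimed
  visited <- logical(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    nb <- neigh(i)
    if (length(nb) < min_pts) next   # noise (may be claimed later as border)
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nb
    while (length(queue)) {
      j <- queue[[1]]; queue <- queue[-1]
      if (labels[j] == 0L) labels[j] <- cl
      if (visited[j]) next
      visited[j] <- TRUE
      nbj <- neigh(j)
      if (length(nbj) >= min_pts) {    # j is core: expand through it
        labels[nbj[labels[nbj] == 0L]] <- cl
        queue <- c(queue, nbj[!visited[nbj]])
      }
    }
  }
  labels
}

#' Two-round DBSCAN on a UMAP embedding
#'
#' Round 1 (eps 0.5, minPts 50) separates the major clusters; round 2
#' (eps 0.2, minPts 20) resolves subclusters, which are nested into the
#' major clusters by majority overlap. Noise points carry NA.
#'
#' @param embedding n x 2 matrix.
#' @param eps1,min_pts1 round-1 parameters.
#' @param eps2,min_pts2 round-2 parameters.
#' @return data.frame: `major` (integer, NA = noise), `sub` (character
#'   "major.sub", NA = round-2 noise).
#' @export
dbscan_two_rounds <- function(embedding, eps1 = 0.5, min_pts1 = 50L,
                              eps2 = 0.2, min_pts2 = 20L) {
  l1 <- dbscan_cluster(embedding, eps1, min_pts1)
  l2 <- dbscan_cluster(embedding, eps2, min_pts2)
  major <- ifelse(l1 == 0L, NA_integer_, l1)
  sub <- rep(NA_character_, nrow(embedding))
  for (s in setdiff(unique(l2), 0L)) {
    idx <- which(l2 == s)
    host_tab <- table(major[idx], useNA = "no")
    host <- if (length(host_tab)) as.integer(names(which.max(host_tab))) else NA_integer_
    sub[idx] <- if (is.na(host)) NA_character_ else paste0(host, ".", s)
  }
  data.frame(major = major, sub = sub)
}

.CLUSTER_LEVELS <- c("I", "II", "III", "IV", "V-A", "V-BC")

#' Semantic naming of islet clusters
#'
#' Deterministic, data-driven mapping of cluster statistics to the
#' I--V-BC nomenclature: beta+alpha+ clusters split by CD45 burden into I
#' (low) and II (high); beta+alpha- is III; beta-alpha- with low CHGA and
#' PPY content is IV; beta-alpha+ is V, split by residual CD45 into V-A
#' (at least ~1 cell per islet) and V-BC. Clusters that fit no rule are
#' flagged `unresolved` for manual naming.
#'
#' @param stats data.frame with one row per cluster: `cluster`,
#'   `mean_frac_ProINS`, `mean_frac_GCG`, `mean_frac_PPY`,
#'   `mean_frac_CHGA`, `mean_cd45`, `n`.
#' @param positivity hormone positivity boundary on mean fractions (0.01).
#' @param cd45_high CD45 split between I and II (mean cells/islet).
#' @param cd45_residual CD45 split between V-A and V-BC.
#' @param chga_low CHGA mean fraction below which a beta-alpha- cluster
#'   reads as the CHGA-low PPY-high type (IV).
#' @return `stats` with a `label` column (factor, levels I..V-BC plus
#'   `unresolved`).
#' @export
label_clusters <- function(stats, positivity = 0.01, cd45_high = 5,
                           cd45_residual = 1, chga_low = 0.2) {
  if (nrow(stats) == 0L) stop("empty cluster statistics")
  lab <- character(nrow(stats))
  for (k in seq_len(nrow(stats))) {
    s <- stats[k, ]
    beta <- s$mean_frac_ProINS >= positivity
    alpha <- s$mean_frac_GCG >= positivity
    lab[k] <- if (beta && alpha) {
      if (s$mean_cd45 >= cd45_high) "II" else "I"
    } else if (beta && !alpha) {
      "III"
    } else if (!beta && !alpha) {
      if (s$mean_frac_PPY >= positivity && s$mean_frac_CHGA < chga_low) "IV"
      else "unresolved"
    } else {
      if (s$mean_cd45 >= cd45_residual) "V-A" else "V-BC"
    }
  }
  stats$label <- factor(lab, levels = c(.CLUSTER_LEVELS, "unresolved"))
  stats
}

#' Rule-based approximate cluster key
#'
#' A pure decision rule assigning each islet to a major cluster from the
#' standard three-parameter panel (INS, GCG, CD45; PPY optionally
#' distinguishing III from IV in the pancreas head). Positivity is the
#' usual 1% area boundary; the CD45 splits (>= 5 cells for I vs II, >= 1
#' for V-A vs V-BC) are calibration choices exposed as arguments. The rule
#' set is exhaustive and mutually exclusive: every islet receives a key.
#'
#' @param ins_frac,gcg_frac,ppy_frac staining fractions of islet area, in
#'   `[0, 1]`.
#' @param cd45_count islet-associated CD45+ count.
#' @param region pancreas region (accepted for interface symmetry; the
#'   rules are region-independent).
#' @param positivity positivity boundary (0.01).
#' @param cd45_high,cd45_residual CD45 split points.
#' @return factor of key clusters, levels I, II, III, IV, V-A, V-BC.
#' @export
assign_cluster_key <- function(ins_frac, gcg_frac, cd45_count, ppy_frac = 0,
                               region = NULL, positivity = 0.01,
                               cd45_high = 5, cd45_residual = 1) {
  m <- max(length(ins_frac), length(gcg_frac), length(cd45_count),
           length(ppy_frac))
  ins_frac <- rep_len(ins_frac, m); gcg_frac <- rep_len(gcg_frac, m)
  cd45_count <- rep_len(cd45_count, m); ppy_frac <- rep_len(ppy_frac, m)
  if (any(ins_frac < 0 | ins_frac > 1 | gcg_frac < 0 | gcg_frac > 1 |
            ppy_frac < 0 | ppy_frac > 1, na.rm = TRUE))
    stop("staining fractions must lie in [0, 1]")
  ins <- ins_frac >= positivity
  gcg <- gcg_frac >= positivity
  key <- ifelse(ins & gcg, ifelse(cd45_count >= cd45_high, "II", "I"),
         ifelse(ins & !gcg, "III",
         ifelse(!ins & !gcg, "IV",
                ifelse(cd45_count >= cd45_residual, "V-A", "V-BC"))))
  factor(key, levels = .CLUSTER_LEVELS)
}

#' Cluster the islet cohort end to end
#'
#' Convenience wrapper: features -> UMAP -> two-round DBSCAN -> per-cluster
#' statistics -> semantic labels.
#'
#' @param profiles,immune,spatial,circularity as [assemble_features()].
#' @param seed UMAP seed.
#' @param ... passed to [dbscan_two_rounds()].
#' @return list of class `islet_clustering`: `features`, `embedding`,
#'   `clusters` (data.frame major/sub/label/key), `cluster_stats`.
#' @export
cluster_islets <- function(profiles, immune, spatial, circularity,
                           seed = 0L, ...) {
  Z <- assemble_features(profiles, immune, spatial, circularity)
  emb <- embed_umap(Z, seed = seed)
  cl <- dbscan_two_rounds(emb, ...)
  ids <- sort(unique(cl$major[!is.na(cl$major)]))
  st <- do.call(rbind, lapply(ids, function(k) {
    idx <- which(!is.na(cl$major) & cl$major == k)
    data.frame(cluster = k, n = length(idx),
               mean_frac_ProINS = mean(profiles$frac_ProINS[idx]),
               mean_frac_GCG = mean(profiles$frac_GCG[idx]),
               mean_frac_PPY = mean(profiles$frac_PPY[idx]),
               mean_frac_CHGA = mean(profiles$frac_CHGA[idx]),
               mean_cd45 = mean(immune$total_associated[idx]))
  }))
  st <- if (!is.null(st) && nrow(st)) label_clusters(st[st$n >= 3L, , drop = FALSE]) else st
  cl$label <- NA_character_
  if (!is.null(st) && nrow(st)) {
    map <- stats::setNames(as.character(st$label), st$cluster)
    cl$label <- unname(map[as.character(cl$major)])
  }
  cl$key <- assign_cluster_key(profiles$frac_INS, profiles$frac_GCG,
                               immune$total_associated, profiles$frac_PPY)
  structure(list(features = Z, embedding = emb, clusters = cl,
                 cluster_stats = st),
            class = "islet_clustering")
}

#' @export
print.islet_clustering <- function(x, ...) {
  cat("<islet_clustering> ", nrow(x$embedding), " islets, ",
      length(unique(stats::na.omit(x$clusters$major))), " major clusters (",
      sum(is.na(x$clusters$major)), " noise)\n", sep = "")
  if (!is.null(x$cluster_stats) && nrow(x$cluster_stats)) {
    print(x$cluster_stats[, c("cluster", "n", "label")], row.names = FALSE)
  }
  invisible(x)
}
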