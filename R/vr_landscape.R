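#' VR-score configuration
#'
#' Weights and scaling scope for the Valley-Ridge score
#' VR = w_valley * Valley + w_ridge * Ridge. The default weights (0.9, 0.1)
#' make the entropy-derived Valley dominate, with the trajectory-derived
#' Ridge as a tiebreaker. \code{scaling_scope} controls the span over which
#' inverse velocity lengths are min-max scaled before the Ridge medians:
#' \code{"global"} (across all cells of all samples, keeping VR comparable
#' between samples) or \code{"per_sample"}.
#'
#' @param w_valley,w_ridge nonnegative weights (defaults 0.9 and 0.1).
#' @param scaling_scope \code{"global"} or \code{"per_sample"}.
#' @param ridge_aggregation \code{"product_of_medians"} (default: median
#'   scaled inverse velocity times median scaled centrality distance, per
#'   group) or \code{"median_of_products"} (median over cells of the
#'   per-cell product).
#' @return A list of class \code{vr_config}.
#' @export
vr_config <- function(w_valley = 0.9, w_ridge = 0.1,
                      scaling_scope = c("global", "per_sample"),
                      ridge_aggregation = c("product_of_medians",
                                            "median_of_products")) {
  stopifnot(w_valley >= 0, w_ridge >= 0)
  structure(list(w_valley = w_valley, w_ridge = w_ridge,
                 scaling_scope = match.arg(scaling_scope),
                 ridge_aggregation = match.arg(ridge_aggregation)),
            class = "vr_config")
}

#' Min-max scale a vector to [0, 1]
#'
#' (x - min) / (max - min); a constant vector maps to all zeros.
#'
#' @param x finite numeric vector (cap infinities before calling).
#' @return Vector of the same length in [0, 1].
#' @export
scale_unit <- function(x) {
  if (length(x) == 0) stop("cannot scale an empty vector")
  if (any(!is.finite(x))) stop("scale_unit requires finite values")
  rng <- range(x)
  if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else rep(0, length(x))
}

#' Valley component: median CCAT per sample-cluster
#'
#' @param entropy named CCAT vector from \code{\link{compute_ccat}}
#'   (\code{NA} = undefined, excluded from medians).
#' @param cells a \code{\link{cell_table}} covering the same cells.
#' @return data.frame with \code{sample_id}, \code{cluster_id},
#'   \code{valley}, \code{n_cells}; groups with no defined CCAT carry
#'   \code{NA} valley.
#' @export
valley_component <- function(entropy, cells) {
  cells <- cell_table(cells)
  cc <- entropy[match(cells$cell_id, names(entropy))]
  agg <- group_frame(cells)
  agg$valley <- vapply(agg$.idx, function(idx) {
    v <- cc[idx]
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else stats::median(v)
  }, numeric(1))
  agg$.idx <- NULL
  agg
}

group_frame <- function(cells) {
  key <- paste(cells$sample_id, cells$cluster_id, sep = "\r")
  idx <- split(seq_len(nrow(cells)), key)
  first <- vapply(idx, `[`, 0L, 1L)
  data.frame(sample_id = cells$sample_id[first],
             cluster_id = cells$cluster_id[first],
             n_cells = lengths(idx),
             .idx = I(unname(idx)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Ridge component: scaled inverse velocity times centrality
#'
#' Per cell the inverse velocity length 1/L is computed; infinite inverses
#' (cells with L = 0) are capped at the largest finite inverse within the
#' scaling scope, and the capped inverses are min-max scaled to [0, 1]
#' over that scope. The Ridge of a sample-cluster is the product of the
#' group median of the scaled inverse velocities and the group median of
#' the scaled centrality distances, so it is large for clusters whose
#' cells sit still (near steady state) yet spread away from the cluster
#' medoid -- the ridgeline geometry of a landscape apex.
#'
#' @param lengths a \code{velocity_result} from
#'   \code{\link{velocity_lengths}} (or a named length vector).
#' @param centrality output of \code{\link{centrality_distance}}.
#' @param cells a \code{\link{cell_table}}.
#' @param cfg a \code{\link{vr_config}}.
#' @return data.frame with \code{sample_id}, \code{cluster_id},
#'   \code{ridge} in [0, 1], \code{n_cells}.
#' @export
ridge_component <- function(lengths, centrality, cells, cfg = vr_config()) {
  cells <- cell_table(cells)
  len <- if (inherits(lengths, "velocity_result")) lengths$length else lengths
  L <- len[match(cells$cell_id, names(len))]
  if (any(is.na(L))) stop("velocity lengths missing for ",
                          sum(is.na(L)), " cell(s)")
  sc_dist <- centrality$scaled_distance[match(cells$cell_id, centrality$cell_id)]
  if (any(is.na(sc_dist))) stop("centrality missing for ",
                                sum(is.na(sc_dist)), " cell(s)")
  inv <- 1 / L
  scope <- if (cfg$scaling_scope == "global") rep("all", nrow(cells)) else cells$sample_id
  sc_inv <- numeric(nrow(cells))
  for (sc in unique(scope)) {
    i <- scope == sc
    v <- inv[i]
    if (any(!is.finite(v))) {
      cap <- if (any(is.finite(v))) max(v[is.finite(v)]) else 1
      v[!is.finite(v)] <- cap
    }
    sc_inv[i] <- scale_unit(v)
  }
  agg <- group_frame(cells)
  agg$ridge <- vapply(agg$.idx, function(idx) {
    if (cfg$ridge_aggregation == "product_of_medians") {
      stats::median(sc_inv[idx]) * stats::median(sc_dist[idx])
    } else {
      stats::median(sc_inv[idx] * sc_dist[idx])
    }
  }, numeric(1))
  agg$.idx <- NULL
  agg[, c("sample_id", "cluster_id", "ridge", "n_cells")]
}

#' Valley-Ridge (VR) score
#'
#' VR = w_valley * Valley + w_ridge * Ridge per sample-cluster. With the
#' default weights VR ranges over [-0.9, 1.0]; clusters with the highest
#' VR are the landscape apexes (root candidates).
#'
#' Called with two plain numeric vectors it returns the weighted sum
#' directly; called with the data.frames produced by
#' \code{\link{valley_component}} and \code{\link{ridge_component}} it
#' joins them on (sample_id, cluster_id) and returns a VR table.
#'
#' @param valley numeric vector, or valley data.frame.
#' @param ridge numeric vector, or ridge data.frame.
#' @param cfg a \code{\link{vr_config}}.
#' @return Numeric vector, or data.frame with \code{sample_id},
#'   \code{cluster_id}, \code{n_cells}, \code{valley}, \code{ridge},
#'   \code{vr}.
#' @export
vr_score <- function(valley, ridge, cfg = vr_config()) {
  if (is.numeric(valley) && is.numeric(ridge)) {
    return(cfg$w_valley * valley + cfg$w_ridge * ridge)
  }
  kv <- paste(valley$sample_id, valley$cluster_id, sep = "\r")
  kr <- paste(ridge$sample_id, ridge$cluster_id, sep = "\r")
  orphans <- c(setdiff(kv, kr), setdiff(kr, kv))
  if (length(orphans)) {
    stop("valley/ridge group keys do not match; orphan groups: ",
         paste(gsub("\r", ":", orphans), collapse = ", "))
  }
  m <- match(kv, kr)
  data.frame(sample_id = valley$sample_id, cluster_id = valley$cluster_id,
             n_cells = valley$n_cells, valley = valley$valley,
             ridge = ridge$ridge[m],
             vr = cfg$w_valley * valley$valley + cfg$w_ridge * ridge$ridge[m],
             stringsAsFactors = FALSE)
}

#' Landscape height grid from VR scores
#'
#' Every cell carries the VR score of its (sample, cluster); the height of
#' each grid node over the 2D embedding is the Gaussian-kernel-weighted
#' mean of cell VR values (kernel bandwidth in embedding units). Grid
#' nodes with negligible total kernel weight are set to the minimum VR in
#' scope, i.e. unpopulated territory sits at the landscape floor. This is
#' the numeric surface a 3D renderer would display.
#'
#' @param cells a \code{\link{cell_table}} with a 2D embedding.
#' @param vr a VR table from \code{\link{vr_score}}.
#' @param resolution grid nodes per axis (default 50).
#' @param bandwidth Gaussian kernel bandwidth in embedding units.
#' @return A list of class \code{landscape_grid}: \code{grid}
#'   (resolution x resolution heights), \code{x}, \code{y} (node
#'   coordinates), \code{extent}, \code{bandwidth}, \code{apexes} (ranked
#'   cluster ids per sample).
#' @export
landscape_grid <- function(cells, vr, resolution = 50, bandwidth = 0.5) {
  cells <- cell_table(cells)
  if ("dim3" %in% names(cells)) {
    stop("embedding is 3D; project to 2 dimensions (drop dim3) first")
  }
  stopifnot(bandwidth > 0, resolution >= 2)
  key <- paste(cells$sample_id, cells$cluster_id, sep = "\r")
  vr_key <- paste(vr$sample_id, vr$cluster_id, sep = "\r")
  cell_vr <- vr$vr[match(key, vr_key)]
  if (any(is.na(cell_vr))) stop("VR table does not cover every cell's group")
  xr <- range(cells$dim1); yr <- range(cells$dim2)
  gx <- seq(xr[1], xr[2], length.out = resolution)
  gy <- seq(yr[1], yr[2], length.out = resolution)
  grid <- matrix(0, resolution, resolution)
  floor_vr <- min(cell_vr)
  for (iy in seq_len(resolution)) {
    dx <- outer(gx, cells$dim1, `-`)
    dy <- gy[iy] - cells$dim2
    w <- exp(-(sweep(dx^2, 2, dy^2, `+`)) / (2 * bandwidth^2))
    tot <- rowSums(w)
    h <- ifelse(tot > 1e-12, as.numeric(w %*% cell_vr) / tot, floor_vr)
    grid[, iy] <- h
  }
  rk <- rank_apexes_internal(vr)
  structure(list(grid = grid, x = gx, y = gy,
                 extent = c(xmin = xr[1], xmax = xr[2],
                            ymin = yr[1], ymax = yr[2]),
                 bandwidth = bandwidth, apexes = rk),
            class = "landscape_grid")
}

rank_apexes_internal <- function(vr) {
  lapply(split(vr, vr$sample_id), function(df) {
    df$cluster_id[order(-df$vr, df$cluster_id)]
  })
}

#' Apex ranking and cross-sample VR differences
#'
#' Ranks each sample's clusters by VR (descending: rank 1 is the apex /
#' root candidate) and, for clusters shared between the two samples,
#' reports the VR shift delta_vr = VR(sample 2) - VR(sample 1). Clusters
#' present in only one sample are listed separately.
#'
#' @param vr a VR table from \code{\link{vr_score}}.
#' @param samples character vector of exactly two sample ids
#'   (reference first).
#' @return A list with \code{ranking} (named list of cluster ids, VR
#'   descending, per sample), \code{delta} (data.frame cluster_id,
#'   vr_<sample1>, vr_<sample2>, delta_vr), \code{unique} (data.frame
#'   cluster_id, sample_id for sample-unique clusters).
#' @export
rank_apexes <- function(vr, samples) {
  stopifnot(length(samples) == 2)
  missing_s <- setdiff(samples, vr$sample_id)
  if (length(missing_s)) stop("unknown sample id(s): ",
                              paste(missing_s, collapse = ", "))
  vr <- vr[vr$sample_id %in% samples, , drop = FALSE]
  ranking <- rank_apexes_internal(vr)[samples]
  c1 <- vr[vr$sample_id == samples[1], ]
  c2 <- vr[vr$sample_id == samples[2], ]
  shared <- intersect(c1$cluster_id, c2$cluster_id)
  delta <- data.frame(cluster_id = shared,
                      vr_1 = c1$vr[match(shared, c1$cluster_id)],
                      vr_2 = c2$vr[match(shared, c2$cluster_id)],
                      stringsAsFactors = FALSE)
  delta$delta_vr <- delta$vr_2 - delta$vr_1
  names(delta)[2:3] <- paste0("vr_", samples)
  u1 <- setdiff(c1$cluster_id, shared)
  u2 <- setdiff(c2$cluster_id, shared)
  uniq <- data.frame(
    cluster_id = c(u1, u2),
    sample_id = c(rep(samples[1], length(u1)), rep(samples[2], length(u2))),
    stringsAsFactors = FALSE)
  list(ranking = ranking, delta = delta, unique = uniq)
}

#' Run the full cell-plastic-potential pipeline
#'
#' Convenience wrapper: normalize, CCAT, steady-state gamma fit, velocity
#' lengths, centrality distances, Valley/Ridge/VR and apex ranking.
#'
#' @param counts a \code{count_matrix_pair} (QC-filtered).
#' @param cells a \code{\link{cell_table}}.
#' @param degrees gene-degree vector or table (see
#'   \code{\link{compute_ccat}}).
#' @param vr_cfg a \code{\link{vr_config}}.
#' @param velocity_cfg a \code{\link{velocity_config}}.
#' @param knn kNN setting for \code{\link{centrality_distance}}.
#' @return A list with \code{ccat}, \code{velocity}, \code{centrality},
#'   \code{vr} (the VR table) and \code{apexes} (ranking per sample).
#' @export
cpp_pipeline <- function(counts, cells, degrees, vr_cfg = vr_config(),
                         velocity_cfg = velocity_config(), knn = "auto") {
  cells <- cell_table(cells)
  expr <- normalize_log(counts)
  ccat <- compute_ccat(expr, degrees)
  gamma <- fit_gamma(counts, velocity_cfg)
  vel <- velocity_lengths(counts, gamma)
  cent <- centrality_distance(cells, knn = knn)
  valley <- valley_component(ccat, cells)
  ridge <- ridge_component(vel, cent, cells, vr_cfg)
  vr <- vr_score(valley, ridge, vr_cfg)
  list(ccat = ccat, velocity = vel, centrality = cent, vr = vr,
       apexes = rank_apexes_internal(vr))
}
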