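#' Per-cell annotation table
#'
#' Validates the per-cell metadata consumed throughout the pipeline:
#' sample of origin, cluster label, and 2D/3D embedding coordinates
#' (e.g. PHATE), supplied as columns \code{dim1}, \code{dim2}
#' (and optionally \code{dim3}).
#'
#' @param cells data.frame with columns \code{cell_id}, \code{sample_id},
#'   \code{cluster_id}, \code{dim1}, \code{dim2} (optionally \code{dim3}).
#' @return The validated data.frame (invisibly classed \code{cell_table}).
#' @export
cell_table <- function(cells) {
  req <- c("cell_id", "sample_id", "cluster_id", "dim1", "dim2")
  missing_cols <- setdiff(req, names(cells))
  if (length(missing_cols)) {
    stop("cell table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(cells$cell_id)) stop("duplicate cell ids in cell table")
  coord_cols <- intersect(c("dim1", "dim2", "dim3"), names(cells))
  if (!all(vapply(cells[coord_cols], function(v) all(is.finite(v)), TRUE))) {
    stop("non-finite embedding coordinates")
  }
  class(cells) <- unique(c("cell_table", class(cells)))
  cells
}

embedding_cols <- function(cells) intersect(c("dim1", "dim2", "dim3"), names(cells))

#' Size-adaptive kNN default
#'
#' The neighborhood size used by \code{\link{centrality_distance}} adapts
#' to the cluster: 5 percent of the cluster's cells, never fewer than 5 and
#' never more than n - 1 (1 for a singleton cluster).
#'
#' @param n_cluster number of cells in the (sample, cluster) group.
#' @return Positive integer k.
#' @export
default_knn <- function(n_cluster) {
  stopifnot(n_cluster >= 1)
  if (n_cluster == 1) return(1L)
  as.integer(min(n_cluster - 1, max(5, round(0.05 * n_cluster))))
}

#' Within-cluster centrality distance on embedding coordinates
#'
#' For each (sample, cluster) group: a kNN density proxy is computed per
#' cell as the inverse of the mean Euclidean distance to its k nearest
#' neighbors in the embedding; the group medoid is the densest cell (ties
#' broken by lowest cell id); each cell's raw distance is its Euclidean
#' distance to the medoid, and the scaled distance is the min-max scaling
#' of raw distances within the group (all 0 when the group is spatially
#' constant or a singleton).
#'
#' @param cells a \code{\link{cell_table}}.
#' @param knn neighborhood size: a positive integer, or \code{"auto"} to
#'   use \code{\link{default_knn}} per group (default).
#' @return data.frame with columns \code{cell_id}, \code{sample_id},
#'   \code{cluster_id}, \code{raw_distance}, \code{scaled_distance},
#'   \code{knn_used}, in the input cell order.
#' @export
centrality_distance <- function(cells, knn = "auto") {
  cells <- cell_table(cells)
  if (!identical(knn, "auto")) stopifnot(is.numeric(knn), knn >= 1)
  coords <- as.matrix(cells[, embedding_cols(cells), drop = FALSE])
  out <- data.frame(cell_id = cells$cell_id, sample_id = cells$sample_id,
                    cluster_id = cells$cluster_id,
                    raw_distance = NA_real_, scaled_distance = NA_real_,
                    knn_used = NA_integer_, stringsAsFactors = FALSE)
  groups <- split(seq_len(nrow(cells)),
                  list(cells$sample_id, cells$cluster_id), drop = TRUE)
  for (idx in groups) {
    n <- length(idx)
    k <- if (identical(knn, "auto")) default_knn(n) else as.integer(min(knn, max(n - 1, 1)))
    if (n == 1) {
      out$raw_distance[idx] <- 0
      out$scaled_distance[idx] <- 0
      out$knn_used[idx] <- k
      next
    }
    dm <- as.matrix(stats::dist(coords[idx, , drop = FALSE]))
    # mean distance to k nearest neighbors (self excluded)
    mean_knn <- vapply(seq_len(n), function(i) mean(sort(dm[i, -i])[seq_len(k)]),
                       numeric(1))
    density <- ifelse(mean_knn > 0, 1 / mean_knn, Inf)
    best <- which(density == max(density))
    medoid <- best[order(cells$cell_id[idx][best])[1]]
    raw <- dm[, medoid]
    rng <- range(raw)
    scaled <- if (rng[2] > rng[1]) (raw - rng[1]) / (rng[2] - rng[1]) else rep(0, n)
    out$raw_distance[idx] <- raw
    out$scaled_distance[idx] <- scaled
    out$knn_used[idx] <- k
  }
  out
}
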