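#' Spatial-mapping configuration
#'
#' @param rho_min minimum Spearman correlation for a spatial unit to be
#'   assigned a cluster; the threshold is strict (default 0.5: a unit with
#'   best rho exactly 0.5 is left unassigned).
#' @param min_shared_genes minimum genes shared between the spatial panel
#'   and the reference centroids (default 50).
#' @return A list of class \code{mapping_config}.
#' @export
mapping_config <- function(rho_min = 0.5, min_shared_genes = 50) {
  stopifnot(rho_min >= -1, rho_min <= 1, min_shared_genes >= 1)
  structure(list(rho_min = rho_min,
                 min_shared_genes = as.integer(min_shared_genes)),
            class = "mapping_config")
}

#' Cluster centroid expression profiles
#'
#' Per-gene mean of normalized log expression over each cluster's cells;
#' the reference profiles the spatial units are correlated against.
#'
#' @param expr cells x genes normalized log expression matrix with cell
#'   ids as rownames.
#' @param cells a \code{\link{cell_table}} (or any data.frame with
#'   \code{cell_id} and \code{cluster_id}).
#' @return clusters x genes matrix with cluster ids as rownames.
#' @export
cluster_centroids <- function(expr, cells) {
  stopifnot(all(c("cell_id", "cluster_id") %in% names(cells)))
  m <- match(cells$cell_id, rownames(expr))
  if (any(is.na(m))) stop("expression matrix lacks ", sum(is.na(m)),
                          " cell(s) of the cell table")
  x <- expr[m, , drop = FALSE]
  sums <- rowsum(x, cells$cluster_id)
  n <- table(cells$cluster_id)[rownames(sums)]
  if (any(n == 0)) stop("empty cluster(s)")
  sums / as.vector(n)
}

#' Assign spatial units to scRNA-seq clusters by Spearman correlation
#'
#' Each spatial unit's profile is rank-correlated (Spearman, average
#' ranks) against every cluster centroid over the shared genes; the
#' best-correlating cluster is assigned, but the unit is retained only
#' when that correlation strictly exceeds \code{rho_min}. Ties in the
#' argmax are broken toward the lowest cluster id; units whose profile is
#' constant over the shared genes have no defined correlation and are
#' left unassigned.
#'
#' @param profiles units x genes matrix of spatial expression (counts or
#'   normalized; Spearman only uses ranks) with unit ids as rownames.
#' @param centroids clusters x genes centroid matrix from
#'   \code{\link{cluster_centroids}}.
#' @param cfg a \code{\link{mapping_config}}.
#' @return data.frame with \code{unit_id}, \code{best_cluster} (\code{NA}
#'   when not retained), \code{rho} (best correlation; \code{NA} when
#'   undefined), \code{retained}; attribute \code{shared_genes}.
#' @export
map_spatial_to_clusters <- function(profiles, centroids,
                                    cfg = mapping_config()) {
  shared <- intersect(colnames(profiles), colnames(centroids))
  if (length(shared) < cfg$min_shared_genes) {
    stop("only ", length(shared), " genes shared between spatial panel and ",
         "centroids; need at least ", cfg$min_shared_genes)
  }
  p <- profiles[, shared, drop = FALSE]
  ct <- centroids[, shared, drop = FALSE]
  ord <- order(rownames(ct))                 # tie-break: lowest cluster id
  ct <- ct[ord, , drop = FALSE]
  # Spearman = Pearson on average ranks
  rank_rows <- function(m) t(apply(m, 1, rank, ties.method = "average"))
  pr <- rank_rows(p)
  cr <- rank_rows(ct)
  rho_mat <- suppressWarnings(stats::cor(t(pr), t(cr)))  # units x clusters
  best_idx <- apply(rho_mat, 1, function(r) {
    if (all(is.na(r))) NA_integer_ else which.max(r)
  })
  rho <- rho_mat[cbind(seq_len(nrow(p)), best_idx)]
  rho[is.na(best_idx)] <- NA_real_
  retained <- !is.na(rho) & rho > cfg$rho_min
  out <- data.frame(
    unit_id = rownames(p),
    best_cluster = ifelse(retained, rownames(ct)[best_idx], NA_character_),
    rho = rho, retained = retained, stringsAsFactors = FALSE)
  attr(out, "shared_genes") <- shared
  out
}

#' Per-clone cluster composition and heterogeneity
#'
#' Over the retained units of each clone: the mapped-cluster proportion
#' vector, the richness (number of distinct clusters) and the Shannon
#' entropy of the composition in nats. Entropy is 0 for a monoclonal
#' composition and ln(richness) for a uniform one.
#'
#' @param mapping output of \code{\link{map_spatial_to_clusters}}.
#' @param clone_labels named (by unit id) clone label per spatial unit.
#' @return A list with \code{summary} (data.frame: \code{clone},
#'   \code{n_retained}, \code{richness}, \code{shannon}; clones without
#'   retained units flagged by \code{n_retained = 0} and \code{NA}
#'   entropy) and \code{composition} (data.frame: \code{clone},
#'   \code{cluster_id}, \code{proportion}).
#' @export
clone_composition <- function(mapping, clone_labels) {
  clones <- sort(unique(as.character(clone_labels)))
  cl_of_unit <- clone_labels[match(mapping$unit_id, names(clone_labels))]
  comp <- list(); summ <- list()
  for (cl in clones) {
    sub <- mapping[mapping$retained & !is.na(cl_of_unit) & cl_of_unit == cl, ]
    if (nrow(sub) == 0) {
      summ[[cl]] <- data.frame(clone = cl, n_retained = 0L, richness = 0L,
                               shannon = NA_real_, stringsAsFactors = FALSE)
      next
    }
    tab <- table(sub$best_cluster)
    pr <- as.numeric(tab) / sum(tab)
    summ[[cl]] <- data.frame(clone = cl, n_retained = nrow(sub),
                             richness = length(tab),
                             shannon = -sum(pr * log(pr)),
                             stringsAsFactors = FALSE)
    comp[[cl]] <- data.frame(clone = cl, cluster_id = names(tab),
                             proportion = pr, stringsAsFactors = FALSE)
  }
  list(summary = do.call(rbind, c(summ, list(make.row.names = FALSE))),
       composition = if (length(comp)) {
         do.call(rbind, c(comp, list(make.row.names = FALSE)))
       } else NULL)
}
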