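#' Per-sample cluster counts and proportions
#'
#' Counts cells per (sample, cluster) over the union of clusters observed
#' in any sample; clusters absent from a sample are reported with count 0.
#' Proportions are of the sample total.
#'
#' @param cells a \code{\link{cell_table}} (embedding columns optional
#'   here; any data.frame with \code{cell_id}, \code{sample_id},
#'   \code{cluster_id} is accepted).
#' @return data.frame with \code{sample_id}, \code{cluster_id},
#'   \code{count}, \code{proportion}; per-sample proportions sum to 1.
#' @export
cluster_proportions <- function(cells) {
  stopifnot(nrow(cells) > 0,
            all(c("sample_id", "cluster_id") %in% names(cells)))
  tab <- table(sample_id = cells$sample_id, cluster_id = cells$cluster_id)
  out <- as.data.frame(tab, stringsAsFactors = FALSE,
                       responseName = "count")
  totals <- rowSums(tab)
  out$proportion <- out$count / totals[out$sample_id]
  out[order(out$sample_id, out$cluster_id), , drop = FALSE]
}

#' Cluster proportion differences between two samples
#'
#' For each cluster in the union of the two composition tables, the
#' proportion shift delta = proportion_b - proportion_a, plus the fold
#' change b/a (with a flag where the reference proportion is 0 and the
#' fold is undefined).
#'
#' @param a,b composition tables from \code{\link{cluster_proportions}},
#'   each restricted to (or containing) one sample. If a table holds
#'   several samples it must be pre-filtered.
#' @return data.frame with \code{cluster_id}, \code{prop_a},
#'   \code{prop_b}, \code{delta}, \code{fold}, \code{fold_defined}.
#'   Deltas over the union sum to 0.
#' @export
proportion_difference <- function(a, b) {
  one_sample <- function(x, nm) {
    if (length(unique(x$sample_id)) > 1) {
      stop("composition table '", nm, "' holds several samples; filter first")
    }
    x
  }
  a <- one_sample(a, "a"); b <- one_sample(b, "b")
  univ <- sort(union(a$cluster_id, b$cluster_id))
  pa <- a$proportion[match(univ, a$cluster_id)]; pa[is.na(pa)] <- 0
  pb <- b$proportion[match(univ, b$cluster_id)]; pb[is.na(pb)] <- 0
  data.frame(cluster_id = univ, prop_a = pa, prop_b = pb,
             delta = pb - pa,
             fold = ifelse(pa > 0, pb / pa, NA_real_),
             fold_defined = pa > 0, stringsAsFactors = FALSE)
}

#' Module-score configuration
#'
#' @param n_bins number of expression bins for control-gene matching
#'   (default 25).
#' @param n_ctrl_per_bin control genes drawn per occupied bin (default 50;
#'   capped at the bin size).
#' @param seed integer seed for control sampling.
#' @return A list of class \code{score_config}.
#' @export
score_config <- function(n_bins = 25, n_ctrl_per_bin = 50, seed = 0) {
  stopifnot(n_bins >= 1, n_ctrl_per_bin >= 1)
  structure(list(n_bins = as.integer(n_bins),
                 n_ctrl_per_bin = as.integer(n_ctrl_per_bin),
                 seed = as.integer(seed)),
            class = "score_config")
}

#' Binned-control gene-set module score
#'
#' Scores each cell for a gene set against expression-matched controls:
#' genes are ranked by mean expression across cells and the ranks cut into
#' \code{n_bins} equal-width bins; from every bin containing a set gene,
#' \code{n_ctrl_per_bin} control genes are sampled (seeded, without
#' replacement, capped at the bin size); the score is the cell's mean
#' expression over the set minus its mean over the controls. Matching
#' controls on expression level removes the depth/abundance component that
#' a raw set mean would carry.
#'
#' @param expr cells x genes normalized log expression matrix.
#' @param gene_set character vector of gene ids.
#' @param cfg a \code{\link{score_config}}.
#' @return Named numeric score per cell, with attributes \code{n_set_used}
#'   and \code{control_genes}.
#' @export
gene_set_score <- function(expr, gene_set, cfg = score_config()) {
  present <- intersect(gene_set, colnames(expr))
  if (length(present) == 0) {
    stop("no gene of the set is in the expression panel; missing: ",
         paste(utils::head(gene_set, 20), collapse = ", "))
  }
  gene_mean <- colMeans(expr)
  rk <- rank(gene_mean, ties.method = "average")
  bins <- if (cfg$n_bins == 1) rep(1L, length(rk)) else
    cut(rk, breaks = cfg$n_bins, labels = FALSE)
  names(bins) <- colnames(expr)
  set_bins <- unique(bins[present])
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)
  ctrl <- unlist(lapply(sort(set_bins), function(b) {
    pool <- names(bins)[bins == b]
    sample(pool, min(cfg$n_ctrl_per_bin, length(pool)))
  }), use.names = FALSE)
  score <- rowMeans(expr[, present, drop = FALSE]) -
    rowMeans(expr[, ctrl, drop = FALSE])
  attr(score, "n_set_used") <- length(present)
  attr(score, "control_genes") <- ctrl
  score
}

#' Cell-cycle phase assignment from S and G2M scores
#'
#' Scores each cell for the S-phase and G2M-phase gene sets with
#' \code{\link{gene_set_score}} and assigns: G1 when both scores are
#' negative, otherwise the phase with the larger score; exact ties between
#' nonnegative S and G2M scores go to S.
#'
#' @param expr cells x genes normalized log expression matrix.
#' @param s_genes,g2m_genes gene id vectors for the two phase programs
#'   (user-supplied; at least one gene of each must be on the panel).
#' @param cfg a \code{\link{score_config}}.
#' @return data.frame with \code{cell_id}, \code{s_score},
#'   \code{g2m_score}, \code{phase} (factor G1/S/G2M).
#' @export
assign_cell_cycle <- function(expr, s_genes, g2m_genes, cfg = score_config()) {
  if (!length(intersect(s_genes, colnames(expr))) &&
      !length(intersect(g2m_genes, colnames(expr)))) {
    stop("neither the S nor the G2M gene list overlaps the expression panel")
  }
  s_score <- gene_set_score(expr, s_genes, cfg)
  g2m_score <- gene_set_score(expr, g2m_genes, cfg)
  phase <- ifelse(s_score < 0 & g2m_score < 0, "G1",
                  ifelse(s_score >= g2m_score, "S", "G2M"))
  data.frame(cell_id = rownames(expr), s_score = as.numeric(s_score),
             g2m_score = as.numeric(g2m_score),
             phase = factor(phase, levels = c("G1", "S", "G2M")),
             stringsAsFactors = FALSE)
}
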