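#' Velocity-model configuration
#'
#' @param extreme_quantile proportion of cells (by spliced + unspliced
#'   abundance, per gene) used for the steady-state fit (default 0.05:
#'   the top 5 percent).
#' @param min_counts minimum per-gene total (spliced + unspliced) counts
#'   required to fit that gene (default 10).
#' @return A list of class \code{velocity_config}.
#' @export
velocity_config <- function(extreme_quantile = 0.05, min_counts = 10) {
  stopifnot(extreme_quantile > 0, extreme_quantile <= 0.5, min_counts >= 0)
  structure(list(extreme_quantile = extreme_quantile,
                 min_counts = min_counts),
            class = "velocity_config")
}

#' Fit per-gene splicing ratios (steady-state model)
#'
#' Under the steady-state model the unspliced abundance of a gene in cells
#' at equilibrium satisfies u = gamma * s, so gamma is estimated by least
#' squares through the origin, gamma = sum(u*s) / sum(s^2), restricted to
#' the "extreme" cells most likely at equilibrium: those whose combined
#' abundance s + u is at or above the upper \code{extreme_quantile}
#' quantile for that gene.
#'
#' Genes with total counts below \code{min_counts}, or with no spliced
#' signal among the selected cells (sum(s^2) = 0), are excluded and
#' reported as \code{NA}.
#'
#' @param counts a QC-filtered \code{count_matrix_pair} (raw counts; the
#'   ratio fit uses untransformed abundances).
#' @param cfg a \code{\link{velocity_config}}.
#' @return Named numeric vector of nonnegative gamma values, \code{NA} for
#'   excluded genes.
#' @export
fit_gamma <- function(counts, cfg = velocity_config()) {
  stopifnot(inherits(counts, "count_matrix_pair"),
            inherits(cfg, "velocity_config"))
  s <- as.matrix(counts$spliced)
  u <- as.matrix(counts$unspliced)
  n_genes <- ncol(s)
  gamma <- rep(NA_real_, n_genes)
  names(gamma) <- counts$gene_ids
  totals <- colSums(s) + colSums(u)
  for (j in seq_len(n_genes)) {
    if (totals[j] < cfg$min_counts) next
    ab <- s[, j] + u[, j]
    thr <- stats::quantile(ab, 1 - cfg$extreme_quantile, names = FALSE)
    sel <- ab >= thr
    ss <- sum(s[sel, j]^2)
    if (ss == 0) next
    gamma[j] <- max(0, sum(u[sel, j] * s[sel, j]) / ss)
  }
  if (all(is.na(gamma))) {
    stop("no fittable genes (all below min_counts or without spliced signal)")
  }
  gamma
}

#' Per-cell velocity vectors and lengths
#'
#' Computes the velocity residual v_ij = u_ij - gamma_j * s_ij over the
#' fitted genes and the per-cell L2 norm L_i = sqrt(sum_j v_ij^2). Lengths
#' are small for cells near attractor / steady states and large for cells
#' in transit between states; only the length enters the Ridge component of
#' the VR score.
#'
#' @param counts a \code{count_matrix_pair} on the same gene panel the
#'   gamma map was fitted on.
#' @param gamma named gamma vector from \code{\link{fit_gamma}} (\code{NA}
#'   entries = excluded genes).
#' @return A list of class \code{velocity_result}: \code{gamma} (fitted
#'   genes only), \code{velocity} (cells x fitted-genes matrix),
#'   \code{length} (named nonnegative vector, one per cell).
#' @export
velocity_lengths <- function(counts, gamma) {
  stopifnot(inherits(counts, "count_matrix_pair"))
  gamma <- gamma[counts$gene_ids[counts$gene_ids %in% names(gamma)]]
  fitted <- names(gamma)[!is.na(gamma)]
  if (length(fitted) == 0) stop("gamma is missing for every gene")
  s <- as.matrix(counts$spliced[, fitted, drop = FALSE])
  u <- as.matrix(counts$unspliced[, fitted, drop = FALSE])
  v <- u - sweep(s, 2, gamma[fitted], `*`)
  len <- sqrt(rowSums(v^2))
  names(len) <- counts$cell_ids
  structure(list(gamma = gamma[fitted], velocity = v, length = len),
            class = "velocity_result")
}

#' @export
print.velocity_result <- function(x, ...) {
  cat("velocity_result: ", nrow(x$velocity), " cells x ",
      ncol(x$velocity), " fitted genes; median length ",
      signif(stats::median(x$length), 4), "\n", sep = "")
  invisible(x)
}
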