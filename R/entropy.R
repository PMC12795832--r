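#' Per-cell CCAT entropy
#'
#' CCAT (Correlation of Connectome and Transcriptome) scores each cell by
#' the Pearson correlation between its normalized log expression profile and
#' the protein-interaction-network degree of the same genes. It is a fast
#' surrogate for signaling entropy: cells running broad, hub-heavy programs
#' (high differentiation potency) correlate positively with network degree,
#' while committed cells running narrow marker programs do not.
#'
#' The gene universe is the intersection of the expression panel and the
#' degree table; at least 3 shared genes are required. Cells whose
#' expression is constant over the shared genes have no defined correlation
#' and are returned as \code{NA} (they are excluded from downstream
#' medians, not imputed as zero).
#'
#' @param expr cells x genes matrix of normalized log expression
#'   (see \code{\link{normalize_log}}), with gene ids as column names.
#' @param degrees per-gene connectome degree: either a named positive
#'   numeric vector or a data.frame with columns \code{gene_id} and
#'   \code{degree}.
#' @return Named numeric vector of CCAT values in [-1, 1] (one per cell,
#'   \code{NA} where undefined), with attribute \code{n_shared_genes}.
#' @export
compute_ccat <- function(expr, degrees) {
  d <- as_degree_vector(degrees)
  shared <- intersect(colnames(expr), names(d))
  if (length(shared) < 3) {
    stop("only ", length(shared), " genes shared between expression panel ",
         "and degree table; need at least 3")
  }
  x <- expr[, shared, drop = FALSE]
  dv <- d[shared]
  # Pearson r of each row against dv, via centered cross-products
  dv_c <- dv - mean(dv)
  row_mean <- rowMeans(x)
  num <- as.numeric(x %*% dv_c)          # sum(x_i * dv_c) = cov numerator
  ss_x <- rowSums(x^2) - length(dv) * row_mean^2
  ss_d <- sum(dv_c^2)
  denom <- sqrt(pmax(ss_x, 0) * ss_d)
  ccat <- ifelse(denom > 0 & ss_x > 1e-12 * pmax(rowSums(x^2), 1),
                 num / denom, NA_real_)
  ccat <- pmin(pmax(ccat, -1), 1)
  names(ccat) <- rownames(x)
  attr(ccat, "n_shared_genes") <- length(shared)
  ccat
}

as_degree_vector <- function(degrees) {
  if (is.data.frame(degrees)) {
    if (!all(c("gene_id", "degree") %in% names(degrees))) {
      stop("degree table needs columns 'gene_id' and 'degree'")
    }
    d <- stats::setNames(degrees$degree, degrees$gene_id)
  } else {
    d <- degrees
  }
  if (is.null(names(d)) || anyDuplicated(names(d))) {
    stop("degrees must carry unique gene names")
  }
  if (any(!is.finite(d)) || any(d <= 0)) stop("degrees must be positive")
  d
}

#' Read a gene-degree table from TSV
#'
#' @param path TSV with header columns \code{gene_id}, \code{degree}.
#' @return Named numeric degree vector.
#' @export
read_degrees <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_degree_vector(tab)
}
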