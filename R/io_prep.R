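#' Bundle spliced and unspliced count matrices
#'
#' Constructs a validated pair of cells x genes count matrices sharing one
#' gene/cell ordering. The spliced layer is the conventional "expression"
#' layer; the unspliced layer carries nascent transcript counts used by the
#' velocity model.
#'
#' @param spliced cells x genes matrix of nonnegative integer counts
#'   (dense or \code{Matrix} sparse).
#' @param unspliced matrix of identical shape and ordering.
#' @param gene_ids character vector of unique gene identifiers, one per
#'   column.
#' @param cell_ids character vector of unique cell identifiers, one per row.
#' @return An object of class \code{count_matrix_pair}: a list with elements
#'   \code{spliced}, \code{unspliced} (both \code{dgCMatrix}),
#'   \code{gene_ids}, \code{cell_ids}.
#' @export
count_matrix_pair <- function(spliced, unspliced, gene_ids, cell_ids) {
  to_sparse <- function(m) {
    methods::as(methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                        "dMatrix"),
                            "generalMatrix"), "CsparseMatrix")
  }
  spliced <- to_sparse(spliced)
  unspliced <- to_sparse(unspliced)
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (!identical(dim(spliced), dim(unspliced))) {
    stop("spliced and unspliced matrices differ in shape: ",
         paste(dim(spliced), collapse = "x"), " vs ",
         paste(dim(unspliced), collapse = "x"))
  }
  if (ncol(spliced) != length(gene_ids)) {
    stop("matrix has ", ncol(spliced), " gene columns but ", length(gene_ids),
         " gene ids were supplied")
  }
  if (nrow(spliced) != length(cell_ids)) {
    stop("matrix has ", nrow(spliced), " cell rows but ", length(cell_ids),
         " cell ids were supplied")
  }
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids: ",
    paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids: ",
    paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))
  if (min(spliced@x, 0) < 0 || min(unspliced@x, 0) < 0) {
    stop("counts must be nonnegative")
  }
  dimnames(spliced) <- dimnames(unspliced) <- list(cell_ids, gene_ids)
  structure(list(spliced = spliced, unspliced = unspliced,
                 gene_ids = gene_ids, cell_ids = cell_ids),
            class = "count_matrix_pair")
}

#' @export
print.count_matrix_pair <- function(x, ...) {
  cat("count_matrix_pair: ", length(x$cell_ids), " cells x ",
      length(x$gene_ids), " genes (spliced + unspliced layers)\n", sep = "")
  invisible(x)
}

#' Read spliced/unspliced counts from MatrixMarket files
#'
#' Reads two MTX matrices (cells x genes) together with one-id-per-line TSV
#' sidecars for genes and cells and returns a validated
#' \code{\link{count_matrix_pair}}.
#'
#' @param spliced_path,unspliced_path paths to MatrixMarket files holding
#'   cells x genes counts.
#' @param genes_path,cells_path paths to sidecar files, one identifier per
#'   line (first tab-separated field is used).
#' @return A \code{count_matrix_pair}.
#' @export
read_counts <- function(spliced_path, unspliced_path, genes_path, cells_path) {
  for (p in c(spliced_path, unspliced_path, genes_path, cells_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  spliced   <- Matrix::readMM(spliced_path)
  unspliced <- Matrix::readMM(unspliced_path)
  gene_ids <- vapply(strsplit(readLines(genes_path), "\t"), `[`, "", 1L)
  cell_ids <- vapply(strsplit(readLines(cells_path), "\t"), `[`, "", 1L)
  if (ncol(spliced) != length(gene_ids)) {
    stop("format error: ", spliced_path, " has ", ncol(spliced),
         " columns but ", genes_path, " lists ", length(gene_ids), " genes")
  }
  if (nrow(spliced) != length(cell_ids)) {
    stop("format error: ", spliced_path, " has ", nrow(spliced),
         " rows but ", cells_path, " lists ", length(cell_ids), " cells")
  }
  if (!identical(dim(spliced), dim(unspliced))) {
    stop("format error: ", unspliced_path, " dimensions (",
         paste(dim(unspliced), collapse = "x"),
         ") do not match ", spliced_path, " (",
         paste(dim(spliced), collapse = "x"), ")")
  }
  count_matrix_pair(spliced, unspliced, gene_ids, cell_ids)
}

#' Write a count pair to MatrixMarket + TSV sidecars
#'
#' Inverse of \code{\link{read_counts}}; writes \code{spliced.mtx},
#' \code{unspliced.mtx}, \code{genes.tsv} and \code{cells.tsv} into
#' \code{dir}.
#'
#' @param counts a \code{count_matrix_pair}.
#' @param dir output directory (created if missing).
#' @return Invisibly, the four file paths.
#' @export
write_counts <- function(counts, dir) {
  stopifnot(inherits(counts, "count_matrix_pair"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("spliced.mtx", "unspliced.mtx",
                            "genes.tsv", "cells.tsv"))
  Matrix::writeMM(counts$spliced, paths[1])
  Matrix::writeMM(counts$unspliced, paths[2])
  writeLines(counts$gene_ids, paths[3])
  writeLines(counts$cell_ids, paths[4])
  invisible(paths)
}

#' Quality-control configuration
#'
#' Thresholds for cell- and gene-level filtering: cells with fewer than
#' \code{min_genes_per_cell} detected genes or a mitochondrial read fraction
#' above \code{max_mito_fraction} are removed, then genes detected in fewer
#' than \code{min_cells_per_gene} of the remaining cells are removed.
#'
#' @param min_genes_per_cell minimum detected genes per cell (default 100;
#'   a cell is kept when it expresses at least this many genes).
#' @param max_mito_fraction maximum tolerated mitochondrial count fraction
#'   (default 0.20; strictly greater is removed).
#' @param min_cells_per_gene minimum cells a gene must be detected in
#'   (default 20).
#' @param mito_prefix gene-name prefix identifying mitochondrial genes
#'   (default \code{"mt-"}).
#' @return A list of class \code{qc_config}.
#' @export
qc_config <- function(min_genes_per_cell = 100, max_mito_fraction = 0.20,
                      min_cells_per_gene = 20, mito_prefix = "mt-") {
  stopifnot(min_genes_per_cell >= 0, min_cells_per_gene >= 0,
            max_mito_fraction >= 0, max_mito_fraction <= 1)
  structure(list(min_genes_per_cell = as.integer(min_genes_per_cell),
                 max_mito_fraction = max_mito_fraction,
                 min_cells_per_gene = as.integer(min_cells_per_gene),
                 mito_prefix = mito_prefix),
            class = "qc_config")
}

#' Filter cells and genes by quality thresholds
#'
#' Removes cells expressing fewer than \code{min_genes_per_cell} genes
#' (count > 0 on the spliced layer) or whose mitochondrial read fraction
#' exceeds \code{max_mito_fraction}, then removes genes detected in fewer
#' than \code{min_cells_per_gene} remaining cells. Both layers are subset by
#' the same masks; surviving cells and genes keep their input order.
#'
#' @param counts a \code{count_matrix_pair}.
#' @param cfg a \code{\link{qc_config}}.
#' @return The filtered \code{count_matrix_pair}, with an attribute
#'   \code{qc_removed} = c(cells = ..., genes = ...) reporting how many of
#'   each were dropped.
#' @export
qc_filter <- function(counts, cfg = qc_config()) {
  stopifnot(inherits(counts, "count_matrix_pair"), inherits(cfg, "qc_config"))
  s <- counts$spliced
  detected <- Matrix::rowSums(s > 0)
  total <- Matrix::rowSums(s)
  mito_genes <- startsWith(counts$gene_ids, cfg$mito_prefix)
  mito <- if (any(mito_genes)) Matrix::rowSums(s[, mito_genes, drop = FALSE]) else 0
  mito_frac <- ifelse(total > 0, mito / total, 0)
  keep_cell <- detected >= cfg$min_genes_per_cell &
    mito_frac <= cfg$max_mito_fraction
  if (!any(keep_cell)) {
    stop("QC removed all ", length(keep_cell), " cells (min detected genes ",
         cfg$min_genes_per_cell, ", max mito fraction ",
         cfg$max_mito_fraction, ")")
  }
  s2 <- s[keep_cell, , drop = FALSE]
  cells_in_gene <- Matrix::colSums(s2 > 0)
  keep_gene <- cells_in_gene >= cfg$min_cells_per_gene
  out <- count_matrix_pair(
    s2[, keep_gene, drop = FALSE],
    counts$unspliced[keep_cell, keep_gene, drop = FALSE],
    counts$gene_ids[keep_gene],
    counts$cell_ids[keep_cell])
  attr(out, "qc_removed") <- c(cells = sum(!keep_cell), genes = sum(!keep_gene))
  out
}

#' Depth-normalize and log-transform spliced counts
#'
#' Scales each cell's spliced counts to a common total (\code{target_sum}),
#' then applies \code{log1p}. This is the expression representation consumed
#' by CCAT, centroids and module scores.
#'
#' @param counts a \code{count_matrix_pair}.
#' @param target_sum per-cell total after depth normalization (default 1e4).
#' @return A dense cells x genes matrix of normalized log expression with
#'   cell/gene dimnames.
#' @export
normalize_log <- function(counts, target_sum = 1e4) {
  stopifnot(inherits(counts, "count_matrix_pair"), target_sum > 0)
  s <- counts$spliced
  total <- Matrix::rowSums(s)
  if (any(total == 0)) {
    stop(sum(total == 0), " cell(s) have zero total counts; run qc_filter() ",
         "before normalization")
  }
  expr <- log1p(as.matrix(s) * (target_sum / total))
  dimnames(expr) <- list(counts$cell_ids, counts$gene_ids)
  expr
}
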