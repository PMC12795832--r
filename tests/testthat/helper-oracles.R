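# Independent brute-force oracles and small fixture builders. Oracles are
# written from the definitions, not from the package internals.

# per-cell Pearson correlation against a degree vector, via stats::cor
oracle_ccat <- function(expr, degrees) {
  shared <- intersect(colnames(expr), names(degrees))
  apply(expr[, shared, drop = FALSE], 1, function(row) {
    if (stats::sd(row) == 0) NA_real_ else stats::cor(row, degrees[shared])
  })
}

# closed-form gamma on the independently selected extreme subset
oracle_gamma <- function(s, u, q = 0.05, min_counts = 10) {
  vapply(seq_len(ncol(s)), function(j) {
    if (sum(s[, j]) + sum(u[, j]) < min_counts) return(NA_real_)
    ab <- s[, j] + u[, j]
    sel <- ab >= stats::quantile(ab, 1 - q, names = FALSE)
    ss <- sum(s[sel, j]^2)
    if (ss == 0) NA_real_ else max(0, sum(u[sel, j] * s[sel, j]) / ss)
  }, numeric(1))
}

# O(n^2) within-group centrality: pairwise distances, density medoid,
# min-max scaled distance to the medoid
oracle_centrality_group <- function(coords, ids, k) {
  n <- nrow(coords)
  if (n == 1) return(data.frame(raw = 0, scaled = 0))
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- sqrt(sum((coords[i, ] - coords[j, ])^2))
  }
  dens <- numeric(n)
  for (i in seq_len(n)) {
    nb <- sort(d[i, -i])[seq_len(k)]
    dens[i] <- if (mean(nb) > 0) 1 / mean(nb) else Inf
  }
  cand <- which(dens == max(dens))
  medoid <- cand[order(ids[cand])[1]]
  raw <- d[, medoid]
  rng <- range(raw)
  scaled <- if (rng[2] > rng[1]) (raw - rng[1]) / (rng[2] - rng[1]) else rep(0, n)
  data.frame(raw = raw, scaled = scaled)
}

# Spearman with average ranks via explicit rank transform + Pearson
oracle_spearman <- function(x, y) {
  stats::cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"))
}

# binned-control module score, reimplemented from the declared protocol
oracle_gene_set_score <- function(expr, gene_set, n_bins, n_ctrl, seed) {
  gm <- colMeans(expr)
  bins <- cut(rank(gm, ties.method = "average"), breaks = n_bins,
              labels = FALSE)
  names(bins) <- colnames(expr)
  present <- intersect(gene_set, colnames(expr))
  set.seed(seed)
  ctrl <- unlist(lapply(sort(unique(bins[present])), function(b) {
    pool <- names(bins)[bins == b]
    sample(pool, min(n_ctrl, length(pool)))
  }), use.names = FALSE)
  rowMeans(expr[, present, drop = FALSE]) -
    rowMeans(expr[, ctrl, drop = FALSE])
}

# small dense count pair with generic gene/cell names
toy_pair <- function(s, u = s, genes = NULL, cells = NULL) {
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(ncol(s)))
  if (is.null(cells)) cells <- sprintf("cell%02d", seq_len(nrow(s)))
  count_matrix_pair(s, u, genes, cells)
}

# cached default simulation (seed 1), shared across test files
sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(seed = 1) {
  key <- paste0("s", seed)
  if (is.null(sim_cache[[key]])) {
    sim_cache[[key]] <- simulate_tree(sim_config(seed = seed))
  }
  sim_cache[[key]]
}
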