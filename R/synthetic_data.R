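#' Simulation configuration for branching-trajectory data
#'
#' Defines a two-sample (wild-type vs knock-out analog) single-cell
#' experiment over a shared cluster tree, with optional KO-unique root
#' clusters. Defaults describe a compact but realistic design: 300 genes,
#' 5 shared clusters of 200 cells on a two-branch tree rooted at
#' \code{c1}, plus one KO-unique root \code{c6}.
#'
#' The generative model ties each assumption of the downstream scoring to
#' a knob: connectome degrees are heavy-tailed with designated hubs
#' (\code{hub_fraction}); root-cluster cells express a broad program with
#' means proportional to degree^\code{alpha} (so their CCAT is high by
#' construction); leaf cells express cluster-specific marker programs
#' uncorrelated with degree; spliced/unspliced counts follow a per-gene
#' splicing ratio, with root and terminal cells at steady state
#' (E[u] = gamma * E[s], low velocity length) and a \code{transitional_frac}
#' of cells in non-root clusters off steady state (high velocity length).
#' Counts are negative binomial with dispersion \code{nb_dispersion}
#' (NB size = 1/dispersion).
#'
#' @param n_genes number of genes (default 300).
#' @param cells_per_cluster cells per cluster per sample (default 200).
#' @param tree two-column matrix or data.frame of parent -> child edges
#'   over cluster ids (default: c1->c2, c2->c3, c2->c4, c3->c5).
#' @param root_clusters root cluster ids shared by both samples
#'   (default "c1").
#' @param samples two sample ids (default c("WT", "KO")).
#' @param ko_extra_roots root-like cluster ids present only in the second
#'   sample (default "c6").
#' @param nb_dispersion negative-binomial dispersion (default 0.5).
#' @param hub_fraction fraction of genes designated connectome hubs
#'   (default 0.1).
#' @param alpha exponent linking root-program means to degree (default 1).
#' @param transitional_frac fraction of non-root-cluster cells placed off
#'   steady state, in transit from the parent cluster (default 0.3).
#' @param seed integer seed; the whole simulation is deterministic given it.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 300, cells_per_cluster = 200,
                       tree = default_tree(), root_clusters = "c1",
                       samples = c("WT", "KO"), ko_extra_roots = "c6",
                       nb_dispersion = 0.5, hub_fraction = 0.1, alpha = 1,
                       transitional_frac = 0.3, seed = 1) {
  tree <- as.data.frame(tree, stringsAsFactors = FALSE)
  names(tree) <- c("parent", "child")
  stopifnot(n_genes >= 20, cells_per_cluster >= 2, length(root_clusters) >= 1,
            hub_fraction > 0, hub_fraction < 1, nb_dispersion > 0,
            length(samples) == 2, transitional_frac >= 0,
            transitional_frac < 1)
  validate_tree(tree, root_clusters)
  structure(list(n_genes = n_genes, cells_per_cluster = cells_per_cluster,
                 tree = tree, root_clusters = root_clusters,
                 samples = samples, ko_extra_roots = ko_extra_roots,
                 nb_dispersion = nb_dispersion, hub_fraction = hub_fraction,
                 alpha = alpha, transitional_frac = transitional_frac,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_tree <- function() {
  data.frame(parent = c("c1", "c2", "c2", "c3"),
             child  = c("c2", "c3", "c4", "c5"),
             stringsAsFactors = FALSE)
}

validate_tree <- function(tree, root_clusters) {
  if (anyDuplicated(tree$child)) stop("invalid tree: a cluster has two parents")
  if (any(tree$parent == tree$child)) stop("invalid tree: self-edge")
  nodes <- union(tree$parent, tree$child)
  roots_in_tree <- setdiff(tree$parent, tree$child)
  if (!all(root_clusters %in% c(nodes, root_clusters))) stop("invalid roots")
  # depth computation doubles as a cycle check
  depth <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
  depth[setdiff(nodes, tree$child)] <- 0
  for (i in seq_len(length(nodes) + 1)) {
    todo <- tree$child[is.na(depth[tree$child]) & !is.na(depth[tree$parent])]
    if (!length(todo)) break
    depth[todo] <- depth[tree$parent[match(todo, tree$child)]] + 1
  }
  if (any(is.na(depth))) stop("invalid tree: cycle or disconnected child")
  invisible(depth)
}

tree_layout <- function(tree) {
  depth <- validate_tree(tree, character(0))
  nodes <- names(depth)
  # deterministic layout: leaves spread on x by discovery order, parents
  # centered over their children
  children <- split(tree$child, tree$parent)
  x <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
  leaves <- setdiff(nodes, tree$parent)
  x[leaves] <- seq_along(leaves)
  for (d in sort(unique(depth), decreasing = TRUE)) {
    for (nd in nodes[depth == d]) {
      if (is.na(x[nd])) x[nd] <- mean(x[children[[nd]]])
    }
  }
  cbind(x = x, y = max(depth) - depth)
}

#' Simulate two-sample branching-trajectory single-cell data
#'
#' Draws spliced/unspliced negative-binomial counts, cluster labels, a 2D
#' embedding, a gene-degree table and generative ground truth (root
#' clusters, pseudotime, steady-state flags) from a \code{\link{sim_config}}.
#' See \code{\link{sim_config}} for the generative model.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return A list with \code{counts} (\code{count_matrix_pair}),
#'   \code{cells} (\code{\link{cell_table}}), \code{degrees} (named
#'   vector), \code{truth} (list: \code{root_clusters} per sample,
#'   \code{pseudotime} and \code{steady_state} named per cell).
#' @export
simulate_tree <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)

  G <- cfg$n_genes
  genes <- sprintf("g%03d", seq_len(G))
  # heavy-tailed connectome degrees with designated hubs
  degrees <- 1 + stats::rgamma(G, shape = 1.2, scale = 4)
  hubs <- sample.int(G, max(1, round(cfg$hub_fraction * G)))
  degrees[hubs] <- degrees[hubs] * stats::runif(length(hubs), 8, 20)
  names(degrees) <- genes

  depth <- validate_tree(cfg$tree, cfg$root_clusters)
  max_depth <- max(depth, 1)
  layout <- tree_layout(cfg$tree)
  extra <- setdiff(cfg$ko_extra_roots, rownames(layout))
  if (length(extra)) {
    # KO-unique roots sit beside the shared root at depth 0
    add <- cbind(x = max(layout[, "x"]) + seq_along(extra),
                 y = max(layout[, "y"]))
    rownames(add) <- extra
    layout <- rbind(layout, add)
    depth[extra] <- 0
  }

  # broad hub-correlated root program vs narrow marker programs
  mu_root <- degrees^cfg$alpha
  mu_root <- mu_root / sum(mu_root)
  clusters <- rownames(layout)
  mu_cluster <- matrix(0, length(clusters), G,
                       dimnames = list(clusters, genes))
  gamma_true <- stats::runif(G, 0.2, 1)
  n_markers <- max(5, round(G * 0.05))
  for (cl in clusters) {
    w <- depth[cl] / max_depth           # 0 at roots, 1 at deepest leaves
    markers <- sample(setdiff(seq_len(G), hubs), n_markers)
    mu_marker <- rep(0.2 / G, G)
    mu_marker[markers] <- 0.8 / n_markers
    mu_cluster[cl, ] <- (1 - w) * mu_root + w * mu_marker
  }

  per_sample_clusters <- list(setdiff(clusters, cfg$ko_extra_roots), clusters)
  names(per_sample_clusters) <- cfg$samples
  size_nb <- 1 / cfg$nb_dispersion
  lib_size <- 2000
  rows <- list(); meta <- list()
  for (smp in cfg$samples) {
    for (cl in per_sample_clusters[[smp]]) {
      n <- cfg$cells_per_cluster
      is_root <- cl %in% c(cfg$root_clusters, cfg$ko_extra_roots)
      n_trans <- if (is_root) 0 else round(cfg$transitional_frac * n)
      trans <- c(rep(TRUE, n_trans), rep(FALSE, n - n_trans))
      pt <- depth[cl] / max_depth - ifelse(trans, 0.5 / max_depth, 0) +
        stats::rnorm(n, 0, 0.02)
      pt <- pmin(pmax(pt, 0), 1)
      mu_s <- matrix(rep(mu_cluster[cl, ], each = n), n, G) * lib_size
      # transitional cells blend toward the parent program
      if (n_trans > 0 && cl %in% cfg$tree$child) {
        parent <- cfg$tree$parent[match(cl, cfg$tree$child)]
        mu_s[trans, ] <- 0.5 * mu_s[trans, , drop = FALSE] +
          0.5 * matrix(rep(mu_cluster[parent, ], each = n_trans),
                       n_trans, G) * lib_size
      }
      # steady state: E[u] = gamma * E[s]; transit: unspliced excess
      mu_u <- sweep(mu_s, 2, gamma_true, `*`) * 0.3
      mu_u[trans, ] <- mu_u[trans, , drop = FALSE] * 4
      s_cnt <- matrix(stats::rnbinom(n * G, mu = mu_s, size = size_nb), n, G)
      u_cnt <- matrix(stats::rnbinom(n * G, mu = mu_u, size = size_nb), n, G)
      # embedding: cluster node position + jitter; transit cells on the edge
      pos <- matrix(rep(layout[cl, ], each = n), n, 2)
      if (n_trans > 0 && cl %in% cfg$tree$child) {
        parent <- cfg$tree$parent[match(cl, cfg$tree$child)]
        pos[trans, ] <- 0.5 * pos[trans, , drop = FALSE] +
          0.5 * matrix(rep(layout[parent, ], each = n_trans), n_trans, 2)
      }
      pos <- pos + matrix(stats::rnorm(2 * n, 0, 0.12), n, 2)
      # non-transitional cells (root, leaf and settled internal cells) are
      # at equilibrium; only cells in transit carry unspliced excess
      steady <- !trans
      rows[[length(rows) + 1]] <- list(s = s_cnt, u = u_cnt)
      meta[[length(meta) + 1]] <- data.frame(
        sample_id = smp, cluster_id = cl, dim1 = pos[, 1], dim2 = pos[, 2],
        pseudotime = pt, steady_state = steady, stringsAsFactors = FALSE)
    }
  }
  s_all <- do.call(rbind, lapply(rows, `[[`, "s"))
  u_all <- do.call(rbind, lapply(rows, `[[`, "u"))
  cells_df <- do.call(rbind, meta)
  cells_df$cell_id <- sprintf("cell%05d", seq_len(nrow(cells_df)))
  counts <- count_matrix_pair(s_all, u_all, genes, cells_df$cell_id)
  cells <- cell_table(cells_df[, c("cell_id", "sample_id", "cluster_id",
                                   "dim1", "dim2")])
  truth <- list(
    root_clusters = stats::setNames(
      list(cfg$root_clusters, c(cfg$root_clusters, cfg$ko_extra_roots)),
      cfg$samples),
    pseudotime = stats::setNames(cells_df$pseudotime, cells_df$cell_id),
    steady_state = stats::setNames(cells_df$steady_state, cells_df$cell_id))
  list(counts = counts, cells = cells, degrees = degrees, truth = truth)
}

#' Simulate a toy spatial section with multi-clone composition
#'
#' Each spatial unit belongs to a clone; it samples a cluster identity
#' from its clone's mixing proportions and draws negative-binomial counts
#' from that cluster's expression program restricted to a gene subpanel
#' (emulating a targeted spatial panel).
#'
#' @param cfg a \code{\link{sim_config}} (supplies the cluster programs).
#' @param cluster_mix clones x clusters matrix of mixing proportions;
#'   rows must sum to 1 and carry clone ids as rownames.
#' @param units_per_clone spatial units per clone (default 300).
#' @param panel_size genes in the spatial subpanel (default 100; the
#'   first \code{panel_size} genes of the simulated panel).
#' @param seed integer seed.
#' @return A list with \code{profiles} (units x panel genes counts),
#'   \code{clone_labels} (named per unit), \code{true_cluster} (named per
#'   unit) and \code{panel} (gene ids).
#' @export
simulate_spatial <- function(cfg = sim_config(), cluster_mix,
                             units_per_clone = 300, panel_size = 100,
                             seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  cluster_mix <- as.matrix(cluster_mix)
  if (is.null(rownames(cluster_mix))) {
    rownames(cluster_mix) <- paste0("clone", seq_len(nrow(cluster_mix)))
  }
  if (any(abs(rowSums(cluster_mix) - 1) > 1e-8)) {
    stop("cluster_mix rows must sum to 1")
  }
  sim <- simulate_tree(cfg)
  clusters_avail <- unique(sim$cells$cluster_id)
  unknown <- setdiff(colnames(cluster_mix), clusters_avail)
  if (length(unknown)) stop("unknown cluster(s) in mix: ",
                            paste(unknown, collapse = ", "))
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  panel <- sim$counts$gene_ids[seq_len(min(panel_size,
                                           length(sim$counts$gene_ids)))]
  # mean program per cluster on the panel, from the simulated counts
  s <- as.matrix(sim$counts$spliced[, panel, drop = FALSE])
  prog <- rowsum(s, sim$cells$cluster_id) /
    as.vector(table(sim$cells$cluster_id)[sort(unique(sim$cells$cluster_id))])
  size_nb <- 1 / cfg$nb_dispersion
  n_units <- units_per_clone * nrow(cluster_mix)
  clone_labels <- rep(rownames(cluster_mix), each = units_per_clone)
  true_cluster <- character(n_units)
  profiles <- matrix(0L, n_units, length(panel),
                     dimnames = list(sprintf("unit%05d", seq_len(n_units)),
                                     panel))
  for (i in seq_len(n_units)) {
    mix <- cluster_mix[clone_labels[i], ]
    cl <- sample(colnames(cluster_mix), 1, prob = mix)
    true_cluster[i] <- cl
    profiles[i, ] <- stats::rnbinom(length(panel), mu = prog[cl, ],
                                    size = size_nb)
  }
  names(clone_labels) <- rownames(profiles)
  names(true_cluster) <- rownames(profiles)
  list(profiles = profiles, clone_labels = clone_labels,
       true_cluster = true_cluster, panel = panel)
}
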