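ref_fixture <- function(n_genes = 60, n_clusters = 3, cells_per = 8,
                        seed = 9) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  cl <- paste0("k", seq_len(n_clusters))
  cells <- data.frame(
    cell_id = sprintf("c%03d", seq_len(n_clusters * cells_per)),
    cluster_id = rep(cl, each = cells_per), stringsAsFactors = FALSE)
  base <- matrix(rexp(n_clusters * n_genes, 0.2), n_clusters, n_genes,
                 dimnames = list(cl, genes))
  expr <- base[cells$cluster_id, ] + matrix(rnorm(nrow(cells) * n_genes,
                                                  0, 0.3),
                                            nrow(cells), n_genes)
  expr <- pmax(expr, 0)
  rownames(expr) <- cells$cell_id
  list(expr = expr, cells = cells, base = base, genes = genes)
}

test_that("centroids are exact per-cluster means", {
  # two cells [0,2] and [2,0] average to [1,1]
  expr <- matrix(c(0, 2, 2, 0), 2, 2,
                 dimnames = list(c("a", "b"), c("g1", "g2")))
  cells <- data.frame(cell_id = c("a", "b"), cluster_id = "k")
  expect_equal(unname(cluster_centroids(expr, cells)["k", ]), c(1, 1))
  # single-cell cluster: centroid is the cell itself
  cells2 <- data.frame(cell_id = c("a", "b"), cluster_id = c("k1", "k2"))
  expect_equal(cluster_centroids(expr, cells2)["k1", ], expr["a", ])
  # random multi-cluster fixture against a groupby-mean oracle
  fx <- ref_fixture()
  got <- cluster_centroids(fx$expr, fx$cells)
  for (cl in rownames(got)) {
    want <- colMeans(fx$expr[fx$cells$cluster_id == cl, , drop = FALSE])
    expect_equal(got[cl, ], want)
  }
})

test_that("Spearman assignment honors the strict 0.5 retention threshold", {
  fx <- ref_fixture()
  centroids <- cluster_centroids(fx$expr, fx$cells)
  cfg <- mapping_config(rho_min = 0.5, min_shared_genes = 10)
  # a unit equal to a centroid maps to it with rho = 1
  prof <- rbind(unit1 = centroids["k2", ])
  m <- map_spatial_to_clusters(prof, centroids, cfg)
  expect_equal(m$rho, 1)
  expect_identical(m$best_cluster, "k2")
  expect_true(m$retained)

  # best rho exactly 0.5 -> unassigned (strictly greater required):
  # ranks (3,2,1,5,4) vs (1,2,3,4,5) give sum(d^2) = 10 and
  # rho = 1 - 6*10/(5*24) = 0.5
  cent5 <- rbind(k1 = c(1, 2, 3, 4, 5)); colnames(cent5) <- paste0("g", 1:5)
  prof5 <- rbind(u1 = c(3, 2, 1, 5, 4)); colnames(prof5) <- paste0("g", 1:5)
  m5 <- map_spatial_to_clusters(prof5, cent5,
                                mapping_config(rho_min = 0.5,
                                               min_shared_genes = 5))
  expect_equal(m5$rho, 0.5)
  expect_false(m5$retained)
  expect_true(is.na(m5$best_cluster))

  # ties in ranks: agreement with the brute-force average-rank oracle
  set.seed(33)
  prof_t <- matrix(sample(0:3, 5 * 30, replace = TRUE), 5, 30,
                   dimnames = list(paste0("u", 1:5),
                                   sprintf("g%03d", 1:30)))
  cent_t <- matrix(sample(0:4, 3 * 30, replace = TRUE), 3, 30,
                   dimnames = list(c("k1", "k2", "k3"),
                                   sprintf("g%03d", 1:30)))
  mt <- map_spatial_to_clusters(prof_t, cent_t,
                                mapping_config(rho_min = -1,
                                               min_shared_genes = 30))
  for (i in 1:5) {
    rhos <- vapply(rownames(cent_t),
                   function(k) oracle_spearman(prof_t[i, ], cent_t[k, ]),
                   numeric(1))
    expect_equal(mt$rho[i], max(rhos), tolerance = 1e-12)
    expect_identical(mt$best_cluster[i],
                     names(rhos)[which.max(rhos)])
  }
  expect_error(map_spatial_to_clusters(prof_t[, 1:20], cent_t,
                                       mapping_config(min_shared_genes = 30)),
               "shared")
})

test_that("rho is invariant under strictly monotone transforms of a profile", {
  fx <- ref_fixture()
  centroids <- cluster_centroids(fx$expr, fx$cells)
  set.seed(41)
  prof <- matrix(rexp(3 * ncol(centroids)), 3,
                 dimnames = list(paste0("u", 1:3), colnames(centroids)))
  cfg <- mapping_config(rho_min = -1, min_shared_genes = 10)
  base <- map_spatial_to_clusters(prof, centroids, cfg)
  warped <- map_spatial_to_clusters(exp(2 * prof) + 1, centroids, cfg)
  expect_equal(warped$rho, base$rho, tolerance = 1e-12)
  expect_identical(warped$best_cluster, base$best_cluster)
  # retained count never increases as the threshold rises
  counts <- vapply(c(-1, 0, 0.3, 0.6, 0.9), function(r) {
    sum(map_spatial_to_clusters(prof, centroids,
                                mapping_config(r, 10))$retained)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("clone composition, richness and Shannon entropy", {
  mapping <- data.frame(
    unit_id = paste0("u", 1:10),
    best_cluster = c(rep("k1", 4), "k1", "k2", "k1", "k2", NA, "k3"),
    rho = c(rep(0.9, 8), 0.2, 0.9),
    retained = c(rep(TRUE, 8), FALSE, TRUE), stringsAsFactors = FALSE)
  clones <- stats::setNames(c(rep("A", 4), rep("B", 4), "C", "C"),
                            paste0("u", 1:10))
  cc <- clone_composition(mapping, clones)
  sA <- cc$summary[cc$summary$clone == "A", ]
  expect_identical(sA$richness, 1L)
  expect_equal(sA$shannon, 0)
  sB <- cc$summary[cc$summary$clone == "B", ]            # 50/50 k1,k2
  expect_identical(sB$richness, 2L)
  expect_equal(sB$shannon, log(2))
  # entropy bounded by log richness
  expect_true(all(cc$summary$shannon <= log(pmax(cc$summary$richness, 1)) +
                    1e-12, na.rm = TRUE))
  # clone with no retained units is flagged
  clones2 <- stats::setNames(rep("Z", 10), paste0("u", 1:10))
  mapping2 <- mapping; mapping2$retained <- FALSE
  cz <- clone_composition(mapping2, clones2)
  expect_identical(cz$summary$n_retained, 0L)
  expect_true(is.na(cz$summary$shannon))
})

test_that("simulated clones are recovered through the full spatial pipeline", {
  cfg <- sim_config(n_genes = 150, cells_per_cluster = 60, seed = 4)
  sim <- simulate_tree(cfg)
  expr <- normalize_log(sim$counts)
  centroids <- cluster_centroids(expr, sim$cells)
  mix <- rbind(cloneA = c(c1 = 0.7, c5 = 0.3),
               cloneB = c(c1 = 0.1, c5 = 0.9))
  sp <- simulate_spatial(cfg, mix, units_per_clone = 400, panel_size = 150,
                         seed = 5)
  m <- map_spatial_to_clusters(log1p(sp$profiles), centroids,
                               mapping_config(rho_min = 0.5,
                                              min_shared_genes = 50))
  cc <- clone_composition(m, sp$clone_labels)
  compA <- cc$composition[cc$composition$clone == "cloneA", ]
  pA <- stats::setNames(compA$proportion, compA$cluster_id)
  # mapped composition tracks the mix (mapping adds its own noise)
  expect_lte(abs(pA["c1"] - 0.7), 0.1)
  # generating mix recovered within +/-0.05 against the generative truth
  truthA <- table(sp$true_cluster[sp$clone_labels == "cloneA"]) / 400
  expect_true(all(abs(truthA[c("c1", "c5")] - c(0.7, 0.3)) <= 0.05))
})
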