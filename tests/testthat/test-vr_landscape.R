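test_that("unit scaling maps min to 0, max to 1, constants to 0", {
  expect_equal(scale_unit(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(scale_unit(c(5, 5, 5)), c(0, 0, 0))
  set.seed(2)
  x <- rnorm(50)
  sx <- scale_unit(x)
  expect_equal(sx[which.min(x)], 0)
  expect_equal(sx[which.max(x)], 1)
  expect_error(scale_unit(numeric(0)), "empty")
  expect_error(scale_unit(c(1, Inf)), "finite")
})

test_that("valley is the per-group median of defined CCAT values", {
  cells <- cell_table(data.frame(
    cell_id = sprintf("c%03d", 1:6), sample_id = "s",
    cluster_id = rep(c("k1", "k2"), each = 3), dim1 = 0, dim2 = 0))
  cc <- stats::setNames(c(0.2, 0.4, 0.6, 0.2, 0.6, NA), cells$cell_id)
  v <- valley_component(cc, cells)
  expect_equal(v$valley[v$cluster_id == "k1"], 0.4)   # odd group
  expect_equal(v$valley[v$cluster_id == "k2"], 0.4)   # even: central mean
  # group with no defined CCAT is flagged NA
  cc2 <- stats::setNames(c(0.1, 0.1, 0.1, NA, NA, NA), cells$cell_id)
  v2 <- valley_component(cc2, cells)
  expect_true(is.na(v2$valley[v2$cluster_id == "k2"]))
  # large group equals the sort-and-pick oracle
  set.seed(31)
  n <- 101
  big <- cell_table(data.frame(cell_id = sprintf("c%03d", 1:n),
                               sample_id = "s", cluster_id = "k",
                               dim1 = 0, dim2 = 0))
  cc3 <- stats::setNames(rnorm(n), big$cell_id)
  expect_equal(valley_component(cc3, big)$valley,
               unname(sort(cc3)[(n + 1) / 2]))
})

test_that("ridge follows the cap-scale-median-product recipe", {
  # worked 6-cell fixture, one cluster, one zero-length cell
  cells <- cell_table(data.frame(
    cell_id = sprintf("c%03d", 1:6), sample_id = "s", cluster_id = "k",
    dim1 = c(0, 1, 2, 3, 4, 5), dim2 = 0))
  L <- stats::setNames(c(0, 1, 2, 4, 5, 10), cells$cell_id)
  cent <- centrality_distance(cells, knn = 2)
  r <- ridge_component(L, cent, cells)
  # by hand: inv = (Inf,1,.5,.25,.2,.1) -> cap Inf at 1 -> (1,1,.5,.25,.2,.1)
  # scaled: (x - .1)/.9; median = mean(.375, .2 scaled) etc.
  inv <- c(1, 1, 0.5, 0.25, 0.2, 0.1)
  sc <- (inv - 0.1) / 0.9
  expect_equal(r$ridge, median(sc) * median(cent$scaled_distance),
               tolerance = 1e-12)
  expect_true(r$ridge >= 0 && r$ridge <= 1)

  # constant lengths in scope scale to 0 -> ridge 0
  Lc <- stats::setNames(rep(3, 6), cells$cell_id)
  expect_equal(ridge_component(Lc, cent, cells)$ridge, 0)
})

test_that("VR is the weighted sum with defaults 0.9/0.1 and respects bounds", {
  expect_identical(vr_score(1, 0), 0.9)
  expect_identical(vr_score(0, 1), 0.1)
  expect_equal(vr_score(0.5, 0.2), 0.47)
  # strictly increasing in each component
  expect_true(vr_score(0.6, 0.3) > vr_score(0.5, 0.3))
  expect_true(vr_score(0.5, 0.4) > vr_score(0.5, 0.3))
  # table join errors on orphan groups
  v <- data.frame(sample_id = "s", cluster_id = c("k1", "k2"),
                  n_cells = c(3, 3), valley = c(0.5, 0.1))
  r <- data.frame(sample_id = "s", cluster_id = "k1", ridge = 0.2,
                  n_cells = 3)
  expect_error(vr_score(v, r), "orphan")
  r2 <- rbind(r, data.frame(sample_id = "s", cluster_id = "k2",
                            ridge = 0.4, n_cells = 3))
  tab <- vr_score(v, r2)
  expect_equal(tab$vr, 0.9 * tab$valley + 0.1 * tab$ridge)
  expect_true(all(tab$vr >= -0.9 & tab$vr <= 1))
})

test_that("landscape heights interpolate group VR values", {
  # single cluster at constant VR: every populated node sits at that height
  set.seed(13)
  cells <- cell_table(data.frame(
    cell_id = sprintf("c%03d", 1:40), sample_id = "s", cluster_id = "k",
    dim1 = rnorm(40), dim2 = rnorm(40)))
  vr <- data.frame(sample_id = "s", cluster_id = "k", n_cells = 40,
                   valley = 0.5, ridge = 0.5, vr = 0.5)
  g <- landscape_grid(cells, vr, resolution = 10, bandwidth = 1)
  expect_equal(as.numeric(g$grid), rep(0.5, 100))

  # two distant clusters: heights at the centers match each cluster's VR
  cells2 <- cell_table(data.frame(
    cell_id = sprintf("c%03d", 1:80), sample_id = "s",
    cluster_id = rep(c("k1", "k2"), each = 40),
    dim1 = c(rnorm(40, 0, 0.1), rnorm(40, 100, 0.1)),
    dim2 = rnorm(80, 0, 0.1)))
  vr2 <- data.frame(sample_id = "s", cluster_id = c("k1", "k2"),
                    n_cells = 40, valley = c(1, 0), ridge = c(0, 1),
                    vr = c(0.9, 0.1))
  g2 <- landscape_grid(cells2, vr2, resolution = 21, bandwidth = 0.5)
  expect_equal(g2$grid[1, 1], 0.9, tolerance = 1e-6)
  expect_equal(g2$grid[21, 1], 0.1, tolerance = 1e-6)
  expect_identical(g2$apexes$s, c("k1", "k2"))

  # bandwidth -> infinity: every height tends to the cell-weighted mean
  g3 <- landscape_grid(cells2, vr2, resolution = 5, bandwidth = 1e6)
  expect_equal(as.numeric(g3$grid), rep(0.5, 25), tolerance = 1e-6)

  cells3d <- cbind(cells, dim3 = 1)
  expect_error(landscape_grid(cell_table(cells3d), vr), "3D")
})

test_that("apex ranking and cross-sample VR differences", {
  vr <- data.frame(
    sample_id = c("A", "A", "B", "B", "B"),
    cluster_id = c("k1", "k2", "k1", "k2", "k9"),
    n_cells = 5, valley = 0, ridge = 0,
    vr = c(0.8, 0.3, 0.6, 0.5, 0.99))
  rk <- rank_apexes(vr, c("A", "B"))
  expect_identical(rk$ranking$A, c("k1", "k2"))
  expect_identical(rk$ranking$B, c("k9", "k1", "k2"))
  expect_equal(rk$delta$delta_vr[rk$delta$cluster_id == "k1"], -0.2)
  expect_equal(rk$delta$delta_vr[rk$delta$cluster_id == "k2"], 0.2)
  expect_identical(rk$unique$cluster_id, "k9")
  expect_identical(rk$unique$sample_id, "B")
  expect_error(rank_apexes(vr, c("A", "Z")), "unknown sample")
})
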