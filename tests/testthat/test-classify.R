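# Classification stage: constant-module filtering, distances, complete
# linkage, dendrogram cuts, PCA and loading diagnostics.

toy_matrix <- function() {
  m <- rbind(gA = c(100, 0, 50, 100),
             gB = c(100, 100, 50, 0),
             gC = c(100, 100, 50, 10))
  colnames(m) <- sprintf("M%05d", 1:4)
  m
}

test_that("constant-module filtering keeps exactly the varying columns", {
  m <- toy_matrix()
  f <- filter_constant_modules(m)
  expect_equal(colnames(f$matrix), c("M00002", "M00004"))
  expect_equal(f$removed, c("M00001", "M00003"))
  expect_equal(rownames(f$matrix), rownames(m))

  # constant at any shared value (0 or 100 alike) is removed
  m2 <- cbind(m, M00005 = c(0, 0, 0))
  expect_true("M00005" %in% filter_constant_modules(m2)$removed)

  # single genome: every module constant, with a warning
  expect_warning(f1 <- filter_constant_modules(m[1, , drop = FALSE]),
                 "single-genome")
  expect_equal(ncol(f1$matrix), 0L)
  expect_equal(length(f1$removed), 4L)
})

test_that("filtering uses stored precision, not display rounding", {
  m <- rbind(g1 = c(a = 200/3, b = 1), g2 = c(a = 66.7, b = 1))
  # 66.666... and 66.7 round to the same display value but differ exactly
  expect_equal(colnames(filter_constant_modules(m)$matrix), "a")
})

test_that("Euclidean distances match a naive double loop", {
  set.seed(5)
  m <- matrix(runif(40, 0, 100), nrow = 5,
              dimnames = list(paste0("g", 1:5), paste0("m", 1:8)))
  d <- euclidean_distances(m)
  naive <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5)
    naive[i, j] <- sqrt(sum((m[i, ] - m[j, ])^2))
  expect_equal(unname(d), naive, tolerance = 1e-9)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 5))

  # identical rows -> zero distance
  m2 <- rbind(m, g6 = m[1, ])
  expect_equal(euclidean_distances(m2)["g1", "g6"], 0)

  # single-axis check
  m3 <- rbind(g1 = c(0, 0), g2 = c(100, 0))
  expect_equal(euclidean_distances(m3)[1, 2], 100)

  expect_error(euclidean_distances(m[1, , drop = FALSE]), "two genomes")
  expect_error(euclidean_distances(m[, 0]), "empty module set")
})

test_that("complete linkage merges by maximum inter-cluster distance", {
  d <- matrix(c(0, 1, 10,
                1, 0, 10,
                10, 10, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- complete_linkage_cluster(d)
  expect_equal(tree$height, c(1, 10))
  first <- sort(tree$labels[-tree$merge[1, ]])
  expect_equal(first, c("A", "B"))

  # heights are monotone non-decreasing for complete linkage
  set.seed(9)
  m <- matrix(runif(200, 0, 100), nrow = 20)
  rownames(m) <- paste0("g", 1:20)
  tree <- complete_linkage_cluster(euclidean_distances(m))
  expect_true(all(diff(tree$height) >= 0))
  expect_equal(nrow(tree$merge), 19L)

  # identical points merge at height zero
  m0 <- matrix(5, nrow = 4, ncol = 3,
               dimnames = list(paste0("g", 1:4), NULL))
  tree0 <- complete_linkage_cluster(euclidean_distances(m0))
  expect_equal(tree0$height, rep(0, 3))

  dbad <- d; dbad[1, 2] <- Inf; dbad[2, 1] <- Inf
  expect_error(complete_linkage_cluster(dbad), "non-finite")
})

test_that("dendrogram cuts cover the degenerate and planted cases", {
  set.seed(13)
  m <- matrix(runif(50, 0, 100), nrow = 5,
              dimnames = list(paste0("g", 1:5), NULL))
  tree <- complete_linkage_cluster(euclidean_distances(m))
  expect_equal(unname(cut_dendrogram(tree, 1)), rep(1L, 5))
  expect_equal(sort(unique(cut_dendrogram(tree, 5))), 1:5)
  expect_error(cut_dendrogram(tree, 0), "between 1 and")
  expect_error(cut_dendrogram(tree, 6), "between 1 and")

  # two well-separated planted groups are recovered at k = 2
  m2 <- rbind(matrix(runif(30, 0, 5), nrow = 6),
              matrix(runif(30, 95, 100), nrow = 6))
  rownames(m2) <- paste0("g", 1:12)
  tree2 <- complete_linkage_cluster(euclidean_distances(m2))
  labs <- cut_dendrogram(tree2, 2)
  expect_equal(length(unique(labs[1:6])), 1L)
  expect_equal(length(unique(labs[7:12])), 1L)
  expect_true(labs[1] != labs[7])
})

test_that("Newick export carries all genome labels", {
  set.seed(17)
  m <- matrix(runif(40, 0, 100), nrow = 5,
              dimnames = list(paste0("genome", 1:5), NULL))
  tree <- complete_linkage_cluster(euclidean_distances(m))
  nwk <- dendrogram_newick(tree)
  expect_match(nwk, "^\\(")
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, rownames(m))
  expect_true(is.numeric(phy$edge.length))
})

test_that("PCA reconstructs the centered matrix and conserves variance", {
  set.seed(19)
  m <- matrix(runif(60, 0, 100), nrow = 6,
              dimnames = list(paste0("g", 1:6), paste0("m", 1:10)))
  pca <- run_pca(m)
  centered <- sweep(m, 2, colMeans(m))
  expect_equal(pca$scores %*% t(pca$loadings), centered, tolerance = 1e-8)
  # orthogonal loadings
  gram <- t(pca$loadings) %*% pca$loadings
  expect_equal(unname(gram), diag(ncol(pca$loadings)), tolerance = 1e-8)
  # variance percentages: non-negative, sum to 100, match total variance
  expect_true(all(pca$variance_explained >= 0))
  expect_equal(sum(pca$variance_explained), 100, tolerance = 1e-8)
  total_var <- sum(apply(centered, 2, function(v) sum(v^2))) / (nrow(m) - 1)
  comp_var <- apply(pca$scores, 2, function(v) sum(v^2)) / (nrow(m) - 1)
  expect_equal(sum(comp_var), total_var, tolerance = 1e-8)
  # sign convention: each column's largest-magnitude loading is positive
  for (j in seq_len(ncol(pca$loadings))) {
    i <- which.max(abs(pca$loadings[, j]))
    expect_gte(pca$loadings[i, j], 0)
  }
})

test_that("collinear data loads 100 percent on PC1", {
  base <- c(10, 20, 30, 40)
  m <- rbind(g1 = 0 * base, g2 = 1 * base, g3 = 2 * base)
  colnames(m) <- paste0("m", 1:4)
  pca <- run_pca(m)
  expect_equal(pca$variance_explained[[1]], 100, tolerance = 1e-8)
})

test_that("PCA rejects degenerate input", {
  m <- matrix(50, nrow = 4, ncol = 3,
              dimnames = list(paste0("g", 1:4), paste0("m", 1:3)))
  expect_error(run_pca(m), "constant matrix")
  expect_error(run_pca(m[1:2, ]), "at least 3 genomes")
})

test_that("top-loading ranking is deterministic with lexicographic ties", {
  set.seed(29)
  m <- matrix(runif(50, 0, 100), nrow = 5,
              dimnames = list(paste0("g", 1:5), sprintf("M%05d", 1:10)))
  pca <- run_pca(m)
  r1 <- top_loading_modules(pca, axis = 1, n = 5)
  r2 <- top_loading_modules(pca, axis = 1, n = 5)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 5L)
  expect_true(all(diff(abs(r1$loading)) <= 1e-12))
  # n beyond module count returns the full ranking
  expect_equal(nrow(top_loading_modules(pca, 1, 99)), 10L)
  expect_error(top_loading_modules(pca, axis = 20), "axis out of range")

  # a single dominant module ranks first
  grp <- rep(c(0, 60), length.out = 5)
  m2 <- cbind(M99999 = grp * 1.5, m[, 1:4] * 0.01 +
                matrix(runif(20), 5, 4))
  rownames(m2) <- paste0("g", 1:5)
  pca2 <- run_pca(m2)
  expect_equal(top_loading_modules(pca2, 1, 1)$module_id, "M99999")
})
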