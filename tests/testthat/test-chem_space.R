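# independent brute-force U-matrix oracle: double loop over neurons and their
# 8 toroidal neighbours
umatrix_bruteforce <- function(grid) {
  w <- grid$weights
  H <- grid$height; W <- grid$width
  out <- matrix(0, H, W)
  for (r in 1:H) for (c in 1:W) {
    k <- (c - 1) * H + r
    tot <- 0
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- ((r - 1 + dr) %% H) + 1
      cc <- ((c - 1 + dc) %% W) + 1
      kk <- (cc - 1) * H + rr
      tot <- tot + sqrt(sum((w[k, ] - w[kk, ])^2))
    }
    out[r, c] <- tot / 8
  }
  out
}

fake_grid <- function(weights, width, height) {
  structure(list(weights = weights, width = width, height = height,
                 periodic = TRUE), class = "som_grid")
}

test_that("U-matrix equals the brute-force 8-neighbour toroidal average", {
  set.seed(42)
  for (dims in list(c(3, 3), c(4, 7), c(10, 10))) {
    g <- fake_grid(matrix(rnorm(dims[1] * dims[2] * 5), dims[1] * dims[2], 5),
                   width = dims[2], height = dims[1])
    u <- compute_umatrix(g)
    expect_lt(max(abs(u - umatrix_bruteforce(g))), 1e-12)
  }
})

test_that("3x3 torus with one hot neuron gives heights 1 and 1/8", {
  w <- matrix(0, 9, 1)
  hot <- 5
  w[hot, ] <- 1
  u <- compute_umatrix(fake_grid(w, 3, 3))
  # on a 3x3 torus every neuron's 8 neighbours are all other neurons
  expect_equal(as.numeric(u)[hot], 1)
  expect_equal(as.numeric(u)[-hot], rep(1 / 8, 8))
})

test_that("uniform weights give a flat zero U-matrix", {
  u <- compute_umatrix(fake_grid(matrix(2, 16, 3), 4, 4))
  expect_true(all(u == 0))
})

test_that("every neuron has exactly 8 distinct toroidal neighbours", {
  for (dims in list(c(3, 3), c(3, 5), c(6, 4))) {
    nb <- pgmpanel:::toroidal_neighbours(dims[2], dims[1])
    expect_equal(ncol(nb), 8)
    expect_true(all(apply(nb, 1, function(r) length(unique(r)) == 8)))
    expect_true(all(nb >= 1 & nb <= dims[1] * dims[2]))
  }
})

test_that("thresholding the hot-neuron U-matrix isolates one cluster", {
  w <- matrix(0, 9, 1); w[5, ] <- 1
  g <- fake_grid(w, 3, 3)
  u <- compute_umatrix(g)
  fp <- matrix(c(0, 1), 2, 1, dimnames = list(c("a", "b"), "bit001"))
  ca <- delineate_clusters(u, g, fp, threshold = 0.5)
  expect_equal(sum(ca$neuron_cluster == 0), 1)   # hot neuron is background
  expect_equal(ca$n_clusters, 1)
  expect_equal(unname(ca$compound_cluster), c(1L, 1L))  # background BMU reattached
})

test_that("a threshold above the maximum height yields a single cluster", {
  set.seed(1)
  g <- fake_grid(matrix(rnorm(25 * 4), 25, 4), 5, 5)
  u <- compute_umatrix(g)
  fp <- matrix(rpois(10 * 4, 1), 10, 4, dimnames = list(paste0("c", 1:10), NULL))
  ca <- delineate_clusters(u, g, fp, threshold = max(u) * 2)
  expect_equal(ca$n_clusters, 1)
  expect_true(all(ca$compound_cluster == 1))
})

test_that("an all-background threshold is rejected", {
  g <- fake_grid(matrix(1:27, 9, 3), 3, 3)
  u <- compute_umatrix(g)
  expect_error(delineate_clusters(u, g, matrix(1, 1, 3), threshold = 1e-9),
               "foreground")
})

test_that("SOM training is deterministic and degenerate input collapses the map", {
  fp <- matrix(2, 20, 6, dimnames = list(paste0("c", 1:20), paste0("b", 1:6)))
  g1 <- train_som(fp, width = 4, height = 4, epochs = 5, seed = 3)
  g2 <- train_som(fp, width = 4, height = 4, epochs = 5, seed = 3)
  expect_identical(g1$weights, g2$weights)
  u <- compute_umatrix(g1)
  expect_lt(max(u), 0.05)  # all inputs identical: near-flat map
})

test_that("well-separated planted clusters land on disjoint map regions", {
  lib <- generate_compound_library(small_spec(n_compounds = 80, n_clusters = 2,
                                              fp_length = 64, seed = 5))
  g <- train_som(lib$fingerprints, width = 8, height = 8, epochs = 10, seed = 5)
  w <- g$weights
  x <- lib$fingerprints; storage.mode(x) <- "double"
  d2 <- -2 * x %*% t(w) + matrix(rowSums(w^2), nrow(x), nrow(w), byrow = TRUE)
  bmu <- apply(d2, 1, which.min)
  # BMU purity: each neuron hosting compounds should be dominated by one label
  tab <- table(bmu, lib$cluster_labels)
  purity <- sum(apply(tab, 1, max)) / sum(tab)
  expect_gte(purity, 0.9)
})

test_that("cluster count is non-increasing in the threshold on a trained map", {
  lib <- generate_compound_library(small_spec(n_compounds = 120, n_clusters = 3,
                                              fp_length = 64, seed = 9))
  g <- train_som(lib$fingerprints, width = 10, height = 10, epochs = 10, seed = 2)
  u <- compute_umatrix(g)
  qs <- quantile(as.numeric(u), c(0.3, 0.5, 0.7, 0.9, 1))
  counts <- sapply(qs + 1e-9, function(th)
    delineate_clusters(u, g, lib$fingerprints, threshold = th)$n_clusters)
  expect_true(all(diff(counts) <= 0))
})

test_that("same seed gives an identical cluster assignment", {
  lib <- generate_compound_library(small_spec(n_compounds = 60, fp_length = 64, seed = 4))
  a <- cluster_compounds(lib$fingerprints, width = 6, height = 6, epochs = 5, seed = 8)
  b <- cluster_compounds(lib$fingerprints, width = 6, height = 6, epochs = 5, seed = 8)
  expect_identical(a$compound_cluster, b$compound_cluster)
})

test_that("circular fingerprints fold structures to the requested bit length", {
  skip_if_not_installed("ChemmineR")
  skip_if_not_installed("ChemmineOB")
  fp <- fingerprints_from_structures(
    smiles = c(methane = "C", ethanol = "CCO", benzene = "c1ccccc1",
               ethanol2 = "CCO"),
    bit_length = 256, radius = 2)
  expect_equal(ncol(fp), 256)
  expect_true(all(fp >= 0))
  # methane: a single heavy atom has exactly one environment (radius 0)
  expect_equal(sum(fp["methane", ] > 0), 1)
  expect_equal(sum(fp["methane", ]), 1)
  # duplicate structures give identical rows
  expect_equal(unname(fp["ethanol", ]), unname(fp["ethanol2", ]))
  # larger molecules touch more bits
  expect_gt(sum(fp["ethanol", ]), sum(fp["methane", ]))
})
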