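test_that("pair descriptors concatenate fingerprint and encoding widths", {
  fx <- small_panel()
  ids <- sort(unique(fx$panel$pairs$cell_line_id))
  enc <- encode_cell_lines(ids, "view", fx$sp$views$expr)
  tab <- build_pair_table(fx$panel, fx$sp$fingerprints, enc)
  expect_equal(ncol(tab$x), 256 + ncol(fx$sp$views$expr))
  expect_equal(nrow(tab$x), nrow(fx$panel$pairs))
  # compound-only table
  tab0 <- build_pair_table(fx$panel, fx$sp$fingerprints, NULL)
  expect_equal(ncol(tab0$x), 256)
})

test_that("pair table covers exactly the observed pairs and flags missing ids", {
  fx <- small_panel()
  fp_short <- fx$sp$fingerprints[-1, , drop = FALSE]
  expect_error(build_pair_table(fx$panel, fp_short), rownames(fx$sp$fingerprints)[1])
  ids <- sort(unique(fx$panel$pairs$cell_line_id))
  enc <- encode_cell_lines(ids[-1], "dirac")
  expect_error(build_pair_table(fx$panel, fx$sp$fingerprints, enc), ids[1])
})

test_that("a forest on a constant target predicts that constant", {
  x <- matrix(rnorm(50 * 5), 50, 5, dimnames = list(NULL, paste0("f", 1:5)))
  tab <- structure(list(x = x, y = rep(5, 50)), class = "pair_table")
  fit <- pgm_fit(tab, model_config(seed = 1))
  expect_equal(predict(fit, x), rep(5, 50), tolerance = 1e-12)
})

test_that("a forest fits an exact linear rule far below the target spread", {
  set.seed(2)
  x <- matrix(runif(300 * 4), 300, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- 3 * x[, 2]
  tab <- structure(list(x = x, y = y), class = "pair_table")
  fit <- pgm_fit(tab, model_config(seed = 1))
  expect_lt(rmse(y, predict(fit, tab)), sd(y) / 10)
})

test_that("predictions are row-independent and shape-checked", {
  set.seed(4)
  x <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, paste0("f", 1:3)))
  tab <- structure(list(x = x, y = rnorm(40)), class = "pair_table")
  fit <- pgm_fit(tab, model_config(seed = 1))
  p <- predict(fit, x)
  expect_length(p, 40)
  expect_true(all(is.finite(p)))
  perm <- sample(40)
  expect_equal(predict(fit, x[perm, ]), p[perm])
  expect_error(predict(fit, x[, 1:2]), "width")
})

test_that("fits are reproducible under a fixed seed", {
  fx <- small_panel()
  tab <- build_pair_table(fx$panel, fx$sp$fingerprints)
  f1 <- pgm_fit(tab, fast_rf(seed = 11))
  f2 <- pgm_fit(tab, fast_rf(seed = 11))
  expect_identical(predict(f1, tab), predict(f2, tab))
})

test_that("SVM tuning evaluates the full 9 x 6 grid and records the choice", {
  set.seed(6)
  x <- matrix(rnorm(60 * 3), 60, 3, dimnames = list(NULL, paste0("f", 1:3)))
  tab <- structure(list(x = x, y = x[, 1] + rnorm(60, 0, 0.1)), class = "pair_table")
  cfg <- model_config("svm", seed = 2)
  expect_length(cfg$c_grid, 9)
  expect_length(cfg$sigma_grid, 6)
  fit <- pgm_fit(tab, cfg)
  expect_equal(nrow(fit$tuning), 54)
  expect_true(all(is.finite(fit$tuning$cv_rmse)))
  expect_true(fit$best$C %in% cfg$c_grid && fit$best$sigma %in% cfg$sigma_grid)
  expect_true(all(is.finite(predict(fit, tab))))
})

test_that("rmse matches hand arithmetic and degenerate cases", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, 2, 3), c(3, 2, 1)), sqrt(8 / 3), tolerance = 1e-12)
  expect_equal(rmse(c(0, 0), c(1, 1)), 1)
  expect_error(rmse(1:3, 1:2), "mismatch")
})

test_that("rmse behaves as a metric on prediction vectors", {
  set.seed(8)
  for (i in 1:50) {
    a <- rnorm(10); b <- rnorm(10); c <- rnorm(10)
    expect_equal(rmse(a, b), rmse(b, a))
    expect_gte(rmse(a, b) + rmse(b, c), rmse(a, c) - 1e-12)
    expect_equal(rmse(a, a), 0)
  }
})

test_that("r2_zero reproduces the worked examples", {
  y <- c(1, 2, 3)
  expect_equal(r2_zero(y, y), 1)
  # predictions at twice the scale: slope through origin restores them
  expect_equal(r2_zero(y, c(2, 4, 6)), 1, tolerance = 1e-12)
  # reversed predictions: s = 5/7, R2_0 = 1 - (336/49)/2
  expect_equal(r2_zero(y, c(3, 2, 1)), 1 - (336 / 49) / 2, tolerance = 1e-12)
  expect_error(r2_zero(c(2, 2), c(1, 2)), "constant")
  expect_error(r2_zero(y, c(0, 0, 0)), "zero")
})

test_that("r2_zero is invariant to positive rescaling of predictions", {
  set.seed(9)
  y <- rnorm(20); p <- rnorm(20)
  for (c in c(0.01, 1, 250)) {
    expect_equal(r2_zero(y, c * p), r2_zero(y, p), tolerance = 1e-10)
  }
})

test_that("metrics match an independently coded brute force on random pairs", {
  # literal transcriptions of the definitions, independent of the package code
  brute_rmse <- function(y, p) {
    tot <- 0
    for (i in seq_along(y)) tot <- tot + (y[i] - p[i])^2
    sqrt(tot / length(y))
  }
  brute_r2zero <- function(y, p) {
    s_num <- 0; s_den <- 0
    for (i in seq_along(y)) { s_num <- s_num + y[i] * p[i]; s_den <- s_den + p[i]^2 }
    s <- s_num / s_den
    ybar <- sum(y) / length(y)
    num <- 0; den <- 0
    for (i in seq_along(y)) {
      num <- num + (y[i] - s * p[i])^2
      den <- den + (y[i] - ybar)^2
    }
    1 - num / den
  }
  set.seed(10)
  for (i in 1:1000) {
    n <- sample(2:30, 1)
    y <- rnorm(n); p <- rnorm(n)
    expect_equal(rmse(y, p), brute_rmse(y, p), tolerance = 1e-10)
    expect_equal(r2_zero(y, p), brute_r2zero(y, p), tolerance = 1e-10)
  }
})
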