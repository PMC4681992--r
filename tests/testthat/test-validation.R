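test_that("pair folds partition the panel", {
  fx <- small_panel()
  plan <- make_splits(fx$panel, "tenfold_pgm", k = 10, seed = 1)
  tests <- lapply(plan$folds, `[[`, "test")
  expect_equal(sort(unlist(tests)), seq_len(nrow(fx$panel$pairs)))
  expect_equal(sum(duplicated(unlist(tests))), 0)
  for (f in plan$folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_setequal(c(f$train, f$test), seq_len(nrow(fx$panel$pairs)))
  }
})

test_that("leave-one-cell-line-out folds test exactly one line each", {
  fx <- small_panel()
  plan <- make_splits(fx$panel, "loco")
  lines <- sort(unique(fx$panel$pairs$cell_line_id))
  expect_length(plan$folds, length(lines))
  for (i in seq_along(plan$folds)) {
    f <- plan$folds[[i]]
    expect_setequal(unique(fx$panel$pairs$cell_line_id[f$test]), lines[i])
    expect_false(lines[i] %in% fx$panel$pairs$cell_line_id[f$train])
  }
})

test_that("leave-one-tissue-out folds hold out all of a tissue's lines jointly", {
  rec <- data.frame(compound_id = rep(paste0("c", 1:5), times = 4),
                    cell_line_id = rep(c("A", "B", "C", "D"), each = 5),
                    pGI50 = rnorm(20, 6))
  tis <- c(A = "t1", B = "t1", C = "t2", D = "t2")
  panel <- aggregate_replicates(rec, tis, 0.27)
  plan <- make_splits(panel, "loto")
  expect_length(plan$folds, 2)
  for (f in plan$folds) {
    held <- unique(panel$pairs$cell_line_id[f$test])
    expect_length(held, 2)
    expect_length(unique(tis[held]), 1)
  }
})

test_that("cluster folds require an assignment and reject an all-covering cluster", {
  fx <- small_panel()
  expect_error(make_splits(fx$panel, "locco"), "cluster_assignment")
  all_one <- structure(list(compound_cluster = setNames(
    rep(1L, length(unique(fx$panel$pairs$compound_id))),
    unique(fx$panel$pairs$compound_id))), class = "cluster_assignment")
  expect_error(make_splits(fx$panel, "locco", clusters = all_one), "empty training")
})

test_that("per-cell-line folds stay inside one line", {
  fx <- small_panel()
  plan <- make_splits(fx$panel, "per_cellline_qsar", k = 5, seed = 2)
  for (f in plan$folds) {
    expect_length(unique(fx$panel$pairs$cell_line_id[c(f$train, f$test)]), 1)
  }
  # per line, the internal folds partition that line's pairs
  p <- fx$panel$pairs
  for (l in unique(p$cell_line_id)) {
    idx <- which(p$cell_line_id == l)
    tested <- unlist(lapply(plan$folds, function(f)
      if (p$cell_line_id[f$test[1]] == l) f$test))
    expect_setequal(tested, idx)
  }
})

test_that("identity encodings refuse cell-line extrapolation strategies", {
  fx <- small_panel()
  ids <- sort(unique(fx$panel$pairs$cell_line_id))
  enc <- encode_cell_lines(ids, "dirac")
  plan <- make_splits(fx$panel, "loco")
  expect_error(run_strategy(fx$panel, fx$sp$fingerprints, enc, plan, fast_rf()),
               "extrapolate")
})

test_that("each eligible pair is predicted exactly once and pooled metrics match", {
  fx <- small_panel()
  plan <- make_splits(fx$panel, "tenfold_pgm", k = 5, seed = 3)
  res <- run_strategy(fx$panel, fx$sp$fingerprints, NULL, plan, fast_rf())
  expect_equal(nrow(res$predictions), nrow(fx$panel$pairs))
  key <- paste(res$predictions$compound_id, res$predictions$cell_line_id)
  expect_equal(sum(duplicated(key)), 0)
  expect_equal(res$pooled$rmse,
               rmse(res$predictions$y_obs, res$predictions$y_pred))
})

test_that("a constant-target panel is reproduced with zero error", {
  rec <- data.frame(compound_id = rep(paste0("c", 1:20), times = 3),
                    cell_line_id = rep(c("A", "B", "C"), each = 20),
                    pGI50 = 5)
  panel <- aggregate_replicates(rec, c(A = "t1", B = "t1", C = "t2"), 0.27)
  fp <- matrix(rpois(20 * 16, 1), 20, 16,
               dimnames = list(paste0("c", 1:20), paste0("b", 1:16)))
  res <- run_strategy(panel, fp, NULL, make_splits(panel, "loco"), fast_rf())
  expect_equal(res$pooled$rmse, 0, tolerance = 1e-12)
})

test_that("groupwise metrics agree with hand-computed per-group values", {
  res <- structure(list(predictions = data.frame(
    compound_id = c("c1", "c2", "c1", "c2"),
    cell_line_id = c("A", "A", "B", "B"),
    fold = 1L, group = "1",
    y_obs = c(5, 6, 7, 8), y_pred = c(5.5, 6, 6, 8.5))),
    class = "strategy_result")
  tab <- groupwise_metrics(res, "cell_line")
  a <- tab[tab$group == "A", ]
  expect_equal(a$rmse, sqrt((0.25 + 0) / 2))
  b <- tab[tab$group == "B", ]
  expect_equal(b$rmse, sqrt((1 + 0.25) / 2))
  # single group equals pooled metrics
  res1 <- res
  res1$predictions$cell_line_id <- "A"
  tab1 <- groupwise_metrics(res1, "cell_line")
  expect_equal(tab1$rmse, rmse(res$predictions$y_obs, res$predictions$y_pred))
  # tiny groups: rmse reported, r2 unavailable
  res2 <- res
  res2$predictions$cell_line_id <- c("A", "B", "B", "B")
  tab2 <- groupwise_metrics(res2, "cell_line")
  expect_true(is.na(tab2$r2_zero[tab2$group == "A"]))
  expect_false(is.na(tab2$rmse[tab2$group == "A"]))
})

test_that("maximum-performance bound equals the uncertainty exactly when it is constant", {
  rec <- data.frame(compound_id = rep(paste0("c", 1:30), 2),
                    cell_line_id = rep(c("A", "B"), each = 30),
                    pGI50 = rnorm(60, 6))
  panel <- aggregate_replicates(rec, c(A = "t1", B = "t2"),
                                default_uncertainty = 0.27)
  b <- performance_bounds(panel, n_rep = 50, seed = 5)
  expect_true(all(abs(b$rmse_max - 0.27) < 1e-12))
  # zero uncertainty: B = A, perfect ceiling
  panel0 <- aggregate_replicates(rec, c(A = "t1", B = "t2"),
                                 default_uncertainty = 0)
  b0 <- performance_bounds(panel0, n_rep = 20, seed = 5)
  expect_true(all(b0$rmse_max == 0))
  expect_true(all(b0$r2_max == 1))
})

test_that("randomized-sample bound sits far below the faithful bound", {
  fx <- small_panel()
  b <- performance_bounds(fx$panel, n_rep = 200, seed = 7)
  expect_lt(median(b$rmse_max), median(b$rmse_min))
  expect_lt(median(b$r2_min), 0)
  expect_gt(median(b$r2_max), 0.8)
})

test_that("an (almost) zero scramble fraction reproduces the unscrambled run", {
  fx <- small_panel()
  cfg <- fast_rf(seed = 2)
  sc <- y_scramble(fx$panel, fx$sp$fingerprints, NULL, fraction = 1e-9,
                   config = cfg, k = 5, seed = 13)
  plan <- make_splits(fx$panel, "tenfold_pgm", k = 5,
                      seed = pgmpanel:::child_seed(13, "scramble_folds"))
  ref <- run_strategy(fx$panel, fx$sp$fingerprints, NULL, plan, cfg)$pooled
  expect_equal(sc, ref)
})

test_that("learning curve trains on the stated fractions and tests on held-out target pairs", {
  fx <- medium_panel()
  lines <- sort(unique(fx$panel$pairs$cell_line_id))
  n_tgt <- sum(fx$panel$pairs$cell_line_id == lines[1])
  n_oth <- nrow(fx$panel$pairs) - n_tgt
  curve <- learning_curve(fx$panel, fx$sp$fingerprints, fx$enc, lines[1],
                          within_fractions = 0.2, across_fractions = c(0, 0.5),
                          config = fast_rf(), n_rep = 2, seed = 3)
  expect_equal(nrow(curve), 4)
  expect_equal(curve$n_train[curve$across == 0], rep(floor(0.2 * n_tgt), 2))
  expect_equal(curve$n_train[curve$across == 0.5],
               rep(floor(0.2 * n_tgt) + floor(0.5 * n_oth), 2))
  expect_true(all(is.finite(curve$rmse)))
  expect_error(learning_curve(fx$panel, fx$sp$fingerprints, fx$enc, lines[1],
                              within_fractions = 1, across_fractions = 0),
               "within")
})

test_that("borrowing data from other cell lines helps a scarce target line", {
  fx <- medium_panel()
  lines <- sort(unique(fx$panel$pairs$cell_line_id))
  curve <- learning_curve(fx$panel, fx$sp$fingerprints, fx$enc, lines[2],
                          within_fractions = 0.05, across_fractions = c(0.05, 1),
                          config = fast_rf(), n_rep = 5, seed = 21)
  m <- aggregate(rmse ~ across, curve, mean)
  expect_lte(m$rmse[m$across == 1], m$rmse[m$across == 0.05])
})
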