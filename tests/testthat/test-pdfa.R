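test_that("balanced_split keeps exact per-cell training counts", {
  d <- data.frame(individual = rep(c("a", "b"), each = 5),
                  context = "beg")
  set.seed(1)
  sp <- balanced_split(d, n_train_per_cell = 3)
  expect_length(sp$train, 6)
  expect_length(sp$test, 4)
  expect_length(intersect(sp$train, sp$test), 0)
  cell <- interaction(d$individual, d$context)[sp$train]
  expect_true(all(table(cell) == 3))
})

test_that("undersized cells are dropped with a warning", {
  d <- data.frame(individual = rep(c("a", "b", "c"), c(5, 5, 2)),
                  context = "beg")
  set.seed(1)
  expect_warning(sp <- balanced_split(d, n_train_per_cell = 3), "dropped")
  expect_identical(sp$dropped, "c:beg")
  expect_false(any(c(11, 12) %in% c(sp$train, sp$test)))
  expect_error(
    suppressWarnings(
      balanced_split(d[d$individual == "c", , drop = FALSE],
                     n_train_per_cell = 3)),
    "no cell")
})

test_that("balanced_split is deterministic under a fixed seed", {
  d <- make_null_calls(1)
  set.seed(99); s1 <- balanced_split(d, n_train_per_cell = 4)
  set.seed(99); s2 <- balanced_split(d, n_train_per_cell = 4)
  expect_identical(s1, s2)
})

test_that("permute_within_blocks conserves block multisets", {
  expect_error(permute_within_blocks(1:3, 1:2), "equal length")
  # blocks of size one cannot move
  set.seed(1)
  expect_identical(permute_within_blocks(letters[1:4], 1:4), letters[1:4])
  # multiset conserved within each block
  labels <- c("A", "A", "B", "C", "C", "C")
  blocks <- c(1, 1, 1, 2, 2, 2)
  for (i in 1:20) {
    out <- permute_within_blocks(labels, blocks)
    expect_setequal(out[1:3], c("A", "A", "B"))
    expect_identical(out[4:6], c("C", "C", "C"))
  }
})

test_that("two-element blocks swap with probability ~ 0.5", {
  set.seed(7)
  swaps <- replicate(10000,
    permute_within_blocks(c("A", "B"), c(1, 1))[1] == "B")
  expect_lt(abs(mean(swaps) - 0.5), 0.02)
})

test_that("fit_and_classify is perfect on separable classes", {
  d <- make_separated_calls(1, sep = 12, n_individuals = 2,
                            calls_per_ind = 20)
  set.seed(2)
  sp <- balanced_split(d, n_train_per_cell = 3)
  res <- fit_and_classify(d[sp$train, ], d[sp$test, ])
  expect_equal(unname(res), c(100, 100))
})

test_that("fit_and_classify rejects degenerate inputs", {
  d <- make_null_calls(1)
  expect_error(fit_and_classify(d, d[0, ]), "empty")
  one <- d[d$individual == "i01", ]
  expect_error(fit_and_classify(one, d), "2 classes")
})

test_that("random labels classify at chance for balanced classes", {
  set.seed(3)
  n <- 1500
  d <- data.frame(individual = rep(sprintf("i%d", 1:5), each = n / 5),
                  matrix(rnorm(n * 8), n, 8,
                         dimnames = list(NULL, acoustic_parameter_names())),
                  check.names = FALSE)
  train_idx <- sample(n, 500)
  res <- fit_and_classify(d[train_idx, ], d[-train_idx, ])
  expect_equal(unname(res["pct_correct_test"]), 20, tolerance = 0.25)
})

test_that("the discriminant core agrees with MASS::lda", {
  skip_if_not_installed("MASS")
  d <- make_separated_calls(4, sep = 1.5)
  pars <- acoustic_parameter_names()
  set.seed(5)
  sp <- suppressWarnings(balanced_split(d, n_train_per_cell = 10))
  train <- d[sp$train, ]; test <- d[sp$test, ]
  fit <- MASS::lda(as.matrix(train[, pars]), grouping = train$individual)
  ref <- as.character(predict(fit, as.matrix(test[, pars]))$class)
  ours <- vocalid:::lda_fit_predict(as.matrix(train[, pars]),
                                    train$individual,
                                    as.matrix(test[, pars]))
  expect_gt(mean(ref == ours), 0.99)
})

test_that("run_pdfa is deterministic and finds strong identity signal", {
  d <- make_separated_calls(6, sep = 5)
  cfg <- pdfa_config(n_permutations = 99, n_selections = 20, seed = 123)
  r1 <- run_pdfa(d, cfg)
  r2 <- run_pdfa(d, cfg)
  expect_identical(r1, r2)
  expect_equal(r1$p_cross, 1 / 100) # minimum attainable with 99 permutations
  expect_equal(r1$p_correct, 1 / 100)
  expect_gt(r1$pct_cross, 90)
  expect_gt(r1$relative_cross, 2)
  expect_identical(r1$n_calls, nrow(d))
  expect_identical(r1$n_context_categories, 3L)
})

test_that("null p-values are approximately uniform (exchangeable splits)", {
  # with a single selection the observed statistic is exchangeable with the
  # null draws, so p should be uniform up to permutation-grid discreteness
  ps <- vapply(1:120, function(r) {
    d <- make_null_calls(1000 + r, n_individuals = 4, n_contexts = 2,
                         calls_per_ind = 12)
    cfg <- pdfa_config(n_permutations = 60, n_selections = 1, seed = r)
    run_pdfa(d, cfg)$p_cross
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("relative cross-classification reproduces reported ratios", {
  expect_equal(relative_cross_classification(44.85, 19.93), 2.25)
  expect_equal(relative_cross_classification(48.89, 25.45), 1.92)
  expect_equal(relative_cross_classification(50, 50), 1.00)
  expect_error(relative_cross_classification(50, 0), "positive")
})

test_that("run_pdfa_by_age_class produces one row per model", {
  d <- make_separated_calls(8, sep = 4, calls_per_ind = 60)
  cfg <- pdfa_config(n_permutations = 19, n_selections = 5, seed = 1)
  tab <- run_pdfa_by_age_class(d, cfg)
  expect_identical(tab$model, c(age_class_labels(), "pooled"))
  expect_identical(tab$n_calls[6], nrow(d))
  expect_equal(sum(tab$n_calls[1:5]), tab$n_calls[6])
  expect_equal(tab$relative_cross,
               round(tab$pct_cross / tab$chance_cross, 2))
})
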