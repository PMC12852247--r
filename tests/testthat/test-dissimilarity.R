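test_that("age classes bin exactly as defined", {
  expect_identical(as.character(assign_age_class(11)), "11-17")
  expect_identical(as.character(assign_age_class(17)), "11-17")
  expect_identical(as.character(assign_age_class(18)), "18-24")
  expect_identical(as.character(assign_age_class(45)), "39-45")
  expect_identical(as.character(assign_age_class(c(14, 21, 28, 35, 42))),
                   age_class_labels())
  expect_error(assign_age_class(46), "within")
  expect_error(assign_age_class(10), "within")
  expect_equal(unname(age_class_midpoints()), c(14, 21, 28, 35, 42))
})

make_profile_calls <- function() {
  pars <- acoustic_parameter_names()
  d <- data.frame(individual = c("a", "a", "a", "b", "b"),
                  age_days = c(12, 12, 12, 12, 12),
                  context = "beg",
                  matrix(1, 5, 8, dimnames = list(NULL, pars)),
                  check.names = FALSE, stringsAsFactors = FALSE)
  d$duration <- c(0.1, 0.2, 0.9, 0.1, 0.3)
  d
}

test_that("daily median profiles use standard sample medians", {
  prof <- daily_median_profiles(make_profile_calls())
  expect_identical(nrow(prof), 2L)
  expect_equal(prof$duration[prof$individual == "a"], 0.2) # odd count
  expect_equal(prof$duration[prof$individual == "b"], 0.2) # even midpoint
  expect_identical(prof$n_calls, c(3L, 2L))
  expect_identical(unique(prof$context), "pooled")
})

test_that("absent strata yield no profile and no dyad", {
  d <- make_profile_calls()
  d$age_days <- c(12, 12, 12, 13, 13) # a and b never share a day
  prof <- daily_median_profiles(d)
  expect_identical(nrow(prof), 2L)
  rec <- dyadic_dissimilarity(prof)
  expect_identical(nrow(rec), 0L)
})

test_that("dyadic scores are Euclidean distances between profiles", {
  pars <- acoustic_parameter_names()
  prof <- data.frame(individual = c("a", "b"), age_days = 12,
                     context = "pooled", n_calls = 1,
                     matrix(0, 2, 8, dimnames = list(NULL, pars)),
                     check.names = FALSE, stringsAsFactors = FALSE)
  prof[2, "q25"] <- 3; prof[2, "q50"] <- 4 # a 3-4-5 triangle
  rec <- dyadic_dissimilarity(prof)
  expect_equal(rec$score, 5)
  expect_identical(rec$dyad, "a|b")

  prof[2, c("q25", "q50")] <- 0 # identical profiles
  expect_equal(dyadic_dissimilarity(prof)$score, 0)
})

test_that("five individuals on a day produce exactly ten dyads", {
  set.seed(1)
  pars <- acoustic_parameter_names()
  prof <- data.frame(individual = sprintf("i%d", 1:5), age_days = 20,
                     context = "pooled", n_calls = 3,
                     matrix(rnorm(40), 5, 8,
                            dimnames = list(NULL, pars)),
                     check.names = FALSE, stringsAsFactors = FALSE)
  rec <- dyadic_dissimilarity(prof)
  expect_identical(nrow(rec), 10L)
  expect_true(all(rec$ind1 < rec$ind2))
})

test_that("scores satisfy the metric axioms on random triples", {
  set.seed(2)
  pars <- acoustic_parameter_names()
  for (i in 1:1000) {
    M <- matrix(rnorm(24), 3, 8, dimnames = list(NULL, pars))
    prof <- data.frame(individual = c("a", "b", "c"), age_days = 15,
                       context = "pooled", n_calls = 1, M,
                       check.names = FALSE, stringsAsFactors = FALSE)
    rec <- dyadic_dissimilarity(prof)
    s <- setNames(rec$score, rec$dyad)
    expect_true(all(s >= 0))
    expect_lte(s["a|c"], s["a|b"] + s["b|c"] + 1e-12)
    # symmetry: score must not depend on the row order of the profiles
    rec2 <- dyadic_dissimilarity(prof[c(3, 1, 2), ])
    expect_equal(setNames(rec2$score, rec2$dyad)[names(s)], s)
  }
})

test_that("max-minus-distance and standardization options work", {
  set.seed(3)
  pars <- acoustic_parameter_names()
  prof <- data.frame(individual = c("a", "b", "c"), age_days = 15,
                     context = "pooled", n_calls = 1,
                     matrix(rnorm(24), 3, 8, dimnames = list(NULL, pars)),
                     check.names = FALSE, stringsAsFactors = FALSE)
  eu <- dyadic_dissimilarity(prof)
  mm <- dyadic_dissimilarity(prof, score = "max-minus-distance")
  expect_equal(mm$score, max(eu$score) - eu$score)
  expect_message(dyadic_dissimilarity(prof, standardize = TRUE),
                 "standardizing")
})

test_that("trend fitting flags insufficient strata and flat data", {
  pars <- acoustic_parameter_names()
  rec <- data.frame(ind1 = "a", ind2 = "b", dyad = "a|b",
                    age_days = c(12, 13, 14, 15), context = "pooled",
                    score = 2, stringsAsFactors = FALSE)
  tr <- dissimilarity_trend(rec)
  expect_equal(tr$slope, 0)
  expect_identical(tr$status, "ok")

  one_age <- rec; one_age$age_days <- 12
  expect_identical(dissimilarity_trend(one_age)$status, "insufficient")
  expect_identical(dissimilarity_trend(rec, context = "move")$status,
                   "insufficient")
})

test_that("divergent age drift is recovered as a positive slope", {
  # clean world: one context, no context effects, no signature offsets, so
  # the only structure is the opposite-sign drift plus within-call noise
  pars <- acoustic_parameter_names()
  zero <- setNames(rep(0, 8), pars)
  drift_a <- zero; drift_a[c("q50", "spectral_centroid")] <- c(12, 12)
  drift_b <- zero; drift_b[c("q50", "spectral_centroid")] <- c(-12, -12)
  sd_w <- default_within_sd()
  ctx <- data.frame(context = "unknown", weight_start = 1, weight_end = 1)
  eff <- matrix(0, 1, 8, dimnames = list("unknown", pars))
  cfg <- generator_config(n_individuals = 2, n_nests = 1,
                          contexts = ctx, context_effects = eff,
                          within_sd = sd_w,
                          calls_per_individual_day = 6,
                          calls_distribution = "fixed", seed = 31)
  prof <- draw_profiles(cfg)
  prof[, paste0("offset_", pars)] <- 0
  prof[1, paste0("drift_", pars)] <- as.list(drift_a)
  prof[2, paste0("drift_", pars)] <- as.list(drift_b)
  d <- generate_dataset(cfg, profiles = prof)
  rec <- dyadic_dissimilarity(daily_median_profiles(d))
  tr <- dissimilarity_trend(rec)
  expect_identical(tr$status, "ok")
  expect_gt(tr$slope, 0)

  # generative expectation by direct Monte Carlo on the stated model:
  # E || delta_drift * (a - 11) + (median noise A - median noise B) ||
  set.seed(99)
  ages <- seq(11, 45)
  delta <- (drift_a - drift_b)
  e_score <- sapply(ages, function(a) {
    mean(replicate(400, {
      eA <- apply(matrix(rnorm(6 * 8, 0, rep(sd_w, each = 6)), 6), 2, median)
      eB <- apply(matrix(rnorm(6 * 8, 0, rep(sd_w, each = 6)), 6), 2, median)
      sqrt(sum((delta * (a - 11) + eA - eB)^2))
    }))
  })
  slope_exp <- ols_trend(e_score, ages)$slope
  se <- summary(stats::lm(score ~ age_days, data = rec))$coefficients[2, 2]
  expect_lt(abs(tr$slope - slope_exp), 2 * se)
})
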