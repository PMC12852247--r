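# Fixture builders shared across test files. All randomness is seeded by the
# caller so individual tests stay reproducible.

# Null calls: no individual signal at all, features pure standard normal.
make_null_calls <- function(seed, n_individuals = 5, n_contexts = 3,
                            calls_per_ind = 40) {
  set.seed(seed)
  n <- n_individuals * calls_per_ind
  ctx <- c("beg", "rest", "move", "unknown", "touch-affiliative",
           "touch-aversive")[seq_len(n_contexts)]
  X <- matrix(rnorm(n * 8), n, 8,
              dimnames = list(NULL, acoustic_parameter_names()))
  data.frame(individual = rep(sprintf("i%02d", seq_len(n_individuals)),
                              each = calls_per_ind),
             context = sample(ctx, n, replace = TRUE),
             age_days = sample(11:45, n, replace = TRUE),
             X, check.names = FALSE, stringsAsFactors = FALSE)
}

# Strongly separated calls: individual mean offsets of `sep` SD units on
# every feature direction (distinct corners), within-SD 1.
make_separated_calls <- function(seed, sep = 5, n_individuals = 5,
                                 calls_per_ind = 40) {
  d <- make_null_calls(seed, n_individuals, 3, calls_per_ind)
  pars <- acoustic_parameter_names()
  offs <- matrix(rnorm(n_individuals * 8, sd = sep), n_individuals, 8)
  ind <- as.integer(factor(d$individual))
  d[, pars] <- d[, pars] + offs[ind, ]
  d
}

# Small synthetic-world config kept cheap for unit tests.
small_generator_config <- function(seed = 1, ...) {
  generator_config(calls_per_individual_day = 3,
                   calls_distribution = "fixed", seed = seed, ...)
}
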