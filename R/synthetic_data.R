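#' Canonical acoustic parameter names
#'
#' The eight per-call descriptors used throughout the package, in canonical
#' order: call duration (s), mean per-frame RMS amplitude (full-scale
#' relative), peak frequency (Hz), the 25th/50th/75th spectral energy
#' quantiles (Hz), spectral centroid (Hz) and spectral slope (dB/kHz).
#'
#' @return Character vector of length 8.
#' @export
acoustic_parameter_names <- function() {
  c("duration", "mean_amplitude", "peak_frequency",
    "q25", "q50", "q75", "spectral_centroid", "spectral_slope")
}

#' Behavioural context labels
#'
#' Context categories recognised by the synthetic generator and the pipeline
#' filters: begging, resting, affiliative touch, aversive touch, feeding,
#' locomotion and unknown.
#'
#' @return Character vector of length 7.
#' @export
context_labels <- function() {
  c("beg", "rest", "touch-affiliative", "touch-aversive",
    "fed", "move", "unknown")
}

#' Default synthetic-world parameter values
#'
#' The stated world of the generator: a broadband juvenile corvid-like call
#' with most energy between roughly 1 and 3 kHz, about 0.3 s long, with a
#' negative spectral tilt. `default_baseline()` gives population means,
#' `default_within_sd()` the call-to-call SDs, `default_offset_sd()` the
#' between-individual signature SDs (roughly half the within-call SD, which
#' yields PIC values a little above 1), `default_drift_sd()` the per-day age
#' drift SDs, `default_context_mixture()` the age-interpolated context
#' weights (begging dominant early, declining with age) and
#' `default_context_effects()` the additive per-context shifts.
#'
#' @return Named numeric 8-vectors, a data frame (mixture), or a context x
#'   parameter matrix (effects).
#' @name generator_defaults
NULL

#' @rdname generator_defaults
#' @export
default_baseline <- function() {
  c(duration = 0.30, mean_amplitude = 0.10, peak_frequency = 1800,
    q25 = 1300, q50 = 1900, q75 = 2700,
    spectral_centroid = 2100, spectral_slope = -8)
}

#' @rdname generator_defaults
#' @export
default_within_sd <- function() {
  c(duration = 0.06, mean_amplitude = 0.030, peak_frequency = 260,
    q25 = 180, q50 = 190, q75 = 220,
    spectral_centroid = 200, spectral_slope = 1.5)
}

#' @rdname generator_defaults
#' @export
default_offset_sd <- function() {
  c(duration = 0.030, mean_amplitude = 0.015, peak_frequency = 130,
    q25 = 90, q50 = 95, q75 = 110,
    spectral_centroid = 100, spectral_slope = 0.8)
}

#' @rdname generator_defaults
#' @export
default_drift_sd <- function() {
  c(duration = 0.0012, mean_amplitude = 0.0006, peak_frequency = 5,
    q25 = 3.5, q50 = 3.5, q75 = 4,
    spectral_centroid = 4, spectral_slope = 0.03)
}

#' @rdname generator_defaults
#' @export
default_context_mixture <- function() {
  data.frame(
    context      = context_labels(),
    weight_start = c(0.55, 0.13, 0.08, 0.05, 0.10, 0.02, 0.07),
    weight_end   = c(0.15, 0.25, 0.13, 0.10, 0.05, 0.15, 0.17),
    stringsAsFactors = FALSE
  )
}

#' @rdname generator_defaults
#' @export
default_context_effects <- function() {
  pars <- acoustic_parameter_names()
  eff <- matrix(0, nrow = 7, ncol = 8,
                dimnames = list(context_labels(), pars))
  eff["beg", ]              <- c( 0.05,  0.020,  150, 120, 130, 150, 140,  0.5)
  eff["rest", ]             <- c(-0.04, -0.025, -120, -90, -90, -90, -90, -0.5)
  eff["touch-affiliative", ] <- c( 0.00, -0.010,  -50, -40, -40, -40, -40, -0.2)
  eff["touch-aversive", ]   <- c( 0.02,  0.015,  200, 150, 160, 180, 170,  0.8)
  eff["fed", ]              <- c(-0.06,  0.005, -200, -150, -160, -170, -160, -1.0)
  eff["move", ]             <- c( 0.01,  0.000,   50,  40,  40,  50,  40,  0.2)
  eff
}

#' Generator configuration for synthetic call datasets
#'
#' Describes a simulated brood: how many individuals in how many nests, the
#' age span in days, the behavioural-context mixture and its change with age,
#' per-context additive effects on the feature vector, and the noise
#' structure (within-call SD, between-individual offset SD, age-drift SD)
#' used when individual profiles are drawn.
#'
#' @param n_individuals Number of individuals (default 5).
#' @param n_nests Number of nests individuals are assigned to (default 2).
#' @param age_range_days Integer vector `c(min, max)`, default `c(11, 45)`.
#' @param contexts Data frame with columns `context`, `weight_start`,
#'   `weight_end` giving the mixture weights at the youngest and oldest age;
#'   weights are linearly interpolated in between and renormalised.
#' @param calls_per_individual_day Either a fixed count or, when
#'   `calls_distribution = "poisson"`, the Poisson mean (default 13).
#' @param calls_distribution `"fixed"` or `"poisson"` (default).
#' @param context_effects Numeric matrix (context x 8 parameters) of additive
#'   shifts; rownames must cover all contexts in `contexts`.
#' @param baseline,within_sd Named 8-vectors: population baseline feature
#'   means and within-individual call-to-call SDs.
#' @param offset_sd,drift_sd Named 8-vectors: SDs used to draw
#'   individual-specific additive offsets and per-day age drifts when
#'   profiles are not supplied explicitly.
#' @param fledge_age_days Age (days) at which phase flips from 1 (nestling)
#'   to 2 (fledgling); default 25.
#' @param sample_rate Sampling rate (Hz) defining the Nyquist bound used for
#'   truncation; default 48000.
#' @param seed Integer RNG seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_individuals = 5,
                             n_nests = 2,
                             age_range_days = c(11L, 45L),
                             contexts = default_context_mixture(),
                             calls_per_individual_day = 13,
                             calls_distribution = c("poisson", "fixed"),
                             context_effects = default_context_effects(),
                             baseline = default_baseline(),
                             within_sd = default_within_sd(),
                             offset_sd = default_offset_sd(),
                             drift_sd = default_drift_sd(),
                             fledge_age_days = 25,
                             sample_rate = 48000,
                             seed = 1L) {
  calls_distribution <- match.arg(calls_distribution)
  pars <- acoustic_parameter_names()
  if (n_individuals < 2) stop("need at least 2 individuals")
  if (n_nests < 1 || n_nests > n_individuals) stop("invalid n_nests")
  age_range_days <- as.integer(age_range_days)
  if (length(age_range_days) != 2L || age_range_days[1] > age_range_days[2])
    stop("age_range_days must be c(min, max) with min <= max")
  if (!is.data.frame(contexts) ||
      !all(c("context", "weight_start", "weight_end") %in% names(contexts)))
    stop("contexts must have columns context, weight_start, weight_end")
  if (nrow(contexts) == 0L) stop("contexts list is empty")
  for (w in c("weight_start", "weight_end")) {
    if (any(contexts[[w]] < 0)) stop("negative context mixture weight")
    if (sum(contexts[[w]]) <= 0) stop("context mixture weights sum to zero")
  }
  if (!all(contexts$context %in% rownames(context_effects)))
    stop("context_effects missing rows for some contexts")
  for (v in list(baseline, within_sd, offset_sd, drift_sd))
    stopifnot(all(pars %in% names(v)))
  if (any(within_sd < 0) || any(offset_sd < 0) || any(drift_sd < 0))
    stop("SDs must be non-negative")
  if (baseline["duration"] <= 0) stop("baseline duration must be positive")
  freq_pars <- c("peak_frequency", "q25", "q50", "q75", "spectral_centroid")
  if (any(baseline[freq_pars] <= 0) || any(baseline[freq_pars] >= sample_rate / 2))
    stop("frequency baselines must lie in (0, Nyquist)")
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_nests = as.integer(n_nests),
    age_range_days = age_range_days,
    contexts = contexts,
    calls_per_individual_day = calls_per_individual_day,
    calls_distribution = calls_distribution,
    context_effects = context_effects[, pars, drop = FALSE],
    baseline = baseline[pars],
    within_sd = within_sd[pars],
    offset_sd = offset_sd[pars],
    drift_sd = drift_sd[pars],
    fledge_age_days = fledge_age_days,
    sample_rate = sample_rate,
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' Draw individual acoustic profiles
#'
#' Each individual gets an additive offset vector (its signature) drawn from
#' `N(0, offset_sd^2)` and a per-day drift vector from `N(0, drift_sd^2)`.
#' Individuals are split across nests as evenly as possible. Uses the current
#' RNG stream.
#'
#' @param config A [generator_config()].
#' @return Data frame with one row per individual: `individual`, `nest`, and
#'   `offset_*` / `drift_*` columns for the 8 parameters.
#' @export
draw_profiles <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  pars <- acoustic_parameter_names()
  n <- config$n_individuals
  ids <- sprintf("ind%02d", seq_len(n))
  nests <- sprintf("nest%d", rep_len(seq_len(config$n_nests), n))
  off <- sapply(pars, function(p) stats::rnorm(n, 0, config$offset_sd[p]))
  dr  <- sapply(pars, function(p) stats::rnorm(n, 0, config$drift_sd[p]))
  out <- data.frame(individual = ids, nest = sort(nests),
                    stringsAsFactors = FALSE)
  colnames(off) <- paste0("offset_", pars)
  colnames(dr)  <- paste0("drift_", pars)
  cbind(out, as.data.frame(off), as.data.frame(dr))
}

context_weights_at_age <- function(contexts, age, age_range) {
  span <- max(1L, diff(age_range))
  frac <- (age - age_range[1]) / span
  w <- contexts$weight_start * (1 - frac) + contexts$weight_end * frac
  w / sum(w)
}

# Validity region for a feature matrix: positive duration, non-negative
# amplitude, frequencies inside (0, Nyquist), ordered energy quantiles.
feature_rows_valid <- function(X, nyquist) {
  freq <- c("peak_frequency", "q25", "q50", "q75", "spectral_centroid")
  ok <- X[, "duration"] > 0 & X[, "mean_amplitude"] >= 0
  for (f in freq) ok <- ok & X[, f] > 0 & X[, f] < nyquist
  ok & X[, "q25"] <= X[, "q50"] & X[, "q50"] <= X[, "q75"]
}

#' Generate a synthetic call dataset
#'
#' Simulates one call table. For each individual and day, the number of calls
#' is fixed or Poisson; each call's behavioural context is drawn from the
#' age-interpolated mixture, and its feature vector is
#' `baseline + individual_offset + age_drift * (age - age_min) + context_effect + noise`,
#' with independent Gaussian noise per parameter (`within_sd`). Draws that
#' leave the valid region (non-positive duration, frequencies outside
#' (0, Nyquist), disordered quantiles) are resampled rather than clipped, so
#' truncation does not pile probability mass on the boundary.
#'
#' Age drift is anchored at the youngest age so that `baseline + offset`
#' describes the individual at study entry.
#'
#' @param config A [generator_config()].
#' @param profiles Optional data frame as returned by [draw_profiles()];
#'   drawn from the config's SDs when `NULL`.
#' @return Data frame with one row per call: `call_id`, `individual`, `nest`,
#'   `context`, `age_days`, `phase`, and the 8 feature columns. Deterministic
#'   given `config$seed`.
#' @export
generate_dataset <- function(config, profiles = NULL) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  if (is.null(profiles)) profiles <- draw_profiles(config)
  pars <- acoustic_parameter_names()
  ages <- seq(config$age_range_days[1], config$age_range_days[2])
  grid <- expand.grid(ind = seq_len(nrow(profiles)), age = ages,
                      KEEP.OUT.ATTRS = FALSE)
  n_calls <- if (config$calls_distribution == "poisson") {
    stats::rpois(nrow(grid), config$calls_per_individual_day)
  } else {
    rep.int(as.integer(config$calls_per_individual_day), nrow(grid))
  }
  idx <- rep(seq_len(nrow(grid)), n_calls)
  ind <- grid$ind[idx]
  age <- grid$age[idx]
  m <- length(idx)
  if (m == 0L) stop("configuration produced zero calls")

  ctx <- character(m)
  for (a in ages) {
    sel <- age == a
    if (!any(sel)) next
    w <- context_weights_at_age(config$contexts, a, config$age_range_days)
    ctx[sel] <- sample(config$contexts$context, sum(sel),
                       replace = TRUE, prob = w)
  }

  off <- as.matrix(profiles[, paste0("offset_", pars)])
  dr  <- as.matrix(profiles[, paste0("drift_", pars)])
  mu <- matrix(config$baseline, m, 8, byrow = TRUE) +
    off[ind, , drop = FALSE] +
    dr[ind, , drop = FALSE] * (age - config$age_range_days[1]) +
    config$context_effects[ctx, , drop = FALSE]
  colnames(mu) <- pars

  draw_noise <- function(k) {
    matrix(stats::rnorm(k * 8, 0, rep(config$within_sd, each = k)), k, 8,
           dimnames = list(NULL, pars))
  }
  X <- mu + draw_noise(m)
  nyq <- config$sample_rate / 2
  bad <- which(!feature_rows_valid(X, nyq))
  tries <- 0L
  while (length(bad) > 0L && tries < 1000L) {
    X[bad, ] <- mu[bad, , drop = FALSE] + draw_noise(length(bad))
    bad <- bad[!feature_rows_valid(X[bad, , drop = FALSE], nyq)]
    tries <- tries + 1L
  }
  if (length(bad) > 0L)
    stop("could not draw valid feature vectors; check baseline/SD config")

  out <- data.frame(
    call_id = sprintf("call_%06d", seq_len(m)),
    individual = profiles$individual[ind],
    nest = profiles$nest[ind],
    context = ctx,
    age_days = age,
    phase = ifelse(age < config$fledge_age_days, 1L, 2L),
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(X))
  attr(out, "seed") <- config$seed
  attr(out, "profiles") <- profiles
  out
}

#' Synthesize a test waveform matching target spectral statistics
#'
#' Builds a band-shaped noise signal whose spectral energy quantiles match
#' the targets by construction: the power spectrum is piecewise constant over
#' four bands `[lo, q25]`, `[q25, q50]`, `[q50, q75]`, `[q75, hi]`, each
#' holding a quarter of the total energy. Random spectral phases give a
#' noise-like waveform; an optional harmonic stack can be mixed in. The
#' signal is scaled so its RMS matches `mean_amplitude` and given short
#' cosine on/off ramps. Intended for round-trip testing of
#' [extract_features()], not for realistic call acoustics.
#'
#' @param target Named vector or list with at least `duration`, `q25`, `q50`,
#'   `q75`; `mean_amplitude` (default 0.1) sets the RMS.
#' @param sample_rate Sampling rate in Hz (default 48000).
#' @param f0 Optional fundamental (Hz) of a harmonic stack mixed with the
#'   noise; `NULL` (default) for pure band noise. Juvenile corvid calls are
#'   broadband and chaotic, so noise alone is the realistic default here.
#' @param harmonic_mix Fraction (0..1) of energy given to the harmonic stack.
#' @param ramp_s Ramp length in seconds (default 0.005).
#' @return Numeric waveform vector of `round(duration * sample_rate)`
#'   samples. Uses the current RNG stream.
#' @export
synthesize_call_waveform <- function(target, sample_rate = 48000,
                                     f0 = NULL, harmonic_mix = 0.3,
                                     ramp_s = 0.005) {
  target <- as.list(target)
  dur <- target$duration
  q <- c(target$q25, target$q50, target$q75)
  if (is.null(dur) || dur <= 0) stop("target duration must be positive")
  if (any(is.na(q)) || length(q) != 3) stop("target must give q25, q50, q75")
  if (is.unsorted(q)) stop("target quantiles must satisfy q25 <= q50 <= q75")
  nyq <- sample_rate / 2
  if (q[3] >= nyq) stop("target q75 must be below Nyquist")
  amp <- if (is.null(target$mean_amplitude)) 0.1 else target$mean_amplitude

  n <- round(dur * sample_rate)
  if (n < 64) stop("duration too short for synthesis at this sample rate")
  wmin <- 25 # floor on band half-width (Hz) so degenerate targets stay usable
  lo <- max(q[1] - max(q[2] - q[1], wmin), 1)
  hi <- min(q[3] + max(q[3] - q[2], wmin), nyq * 0.999)
  edges <- c(lo, q[1], q[2], q[3], hi)
  widths <- pmax(diff(edges), 1e-9)

  freqs <- seq(0, nyq, length.out = floor(n / 2) + 1)
  dens <- numeric(length(freqs))
  for (b in 1:4) {
    sel <- freqs >= edges[b] & freqs < edges[b + 1]
    dens[sel] <- 0.25 / widths[b]
  }
  mag <- sqrt(dens)
  phase <- stats::runif(length(freqs), 0, 2 * pi)
  spec <- mag * exp(1i * phase)
  spec[1] <- 0
  # hermitian-symmetric length-n spectrum -> real waveform
  half <- spec[seq_len(floor(n / 2) + 1)]
  if (n %% 2 == 0) {
    half[length(half)] <- Re(half[length(half)])
    full <- c(half, Conj(rev(half[2:(length(half) - 1)])))
  } else {
    full <- c(half, Conj(rev(half[2:length(half)])))
  }
  x <- Re(stats::fft(full, inverse = TRUE)) / n

  if (!is.null(f0)) {
    stopifnot(f0 > 0, f0 < hi)
    t <- seq_len(n) / sample_rate
    harm <- 0
    for (h in seq(f0, hi, by = f0)) {
      w <- sqrt(dens[which.min(abs(freqs - h))] + 1e-12)
      harm <- harm + w * cos(2 * pi * h * t + stats::runif(1, 0, 2 * pi))
    }
    harm <- harm / max(sqrt(mean(harm^2)), 1e-12)
    x <- sqrt(1 - harmonic_mix) * x / max(sqrt(mean(x^2)), 1e-12) +
      sqrt(harmonic_mix) * harm
  }

  x <- x / max(sqrt(mean(x^2)), 1e-12) * amp
  nr <- min(round(ramp_s * sample_rate), floor(n / 2))
  if (nr > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
    x[seq_len(nr)] <- x[seq_len(nr)] * ramp
    x[(n - nr + 1):n] <- x[(n - nr + 1):n] * rev(ramp)
  }
  x
}

#' Write a call table and optional audio to disk
#'
#' Writes the feature CSV with a `# seed: <seed>` header comment line and,
#' optionally, one synthesized WAV per call plus an annotation CSV.
#'
#' @param calls Data frame from [generate_dataset()].
#' @param path Output CSV path.
#' @param audio_dir Optional directory for per-call WAV files.
#' @param sample_rate Sampling rate for synthesized audio.
#' @return `path`, invisibly.
#' @export
write_call_table <- function(calls, path, audio_dir = NULL,
                             sample_rate = 48000) {
  con <- file(path, "w")
  on.exit(close(con))
  seed <- attr(calls, "seed")
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", seed), con)
  utils::write.csv(calls, con, row.names = FALSE)
  if (!is.null(audio_dir)) {
    dir.create(audio_dir, showWarnings = FALSE, recursive = TRUE)
    ann <- data.frame(file = character(0), call_id = character(0))
    for (i in seq_len(nrow(calls))) {
      wav <- synthesize_call_waveform(calls[i, ], sample_rate)
      f <- file.path(audio_dir, paste0(calls$call_id[i], ".wav"))
      write_wav(wav, sample_rate, f)
      ann <- rbind(ann, data.frame(file = basename(f),
                                   call_id = calls$call_id[i]))
    }
    utils::write.csv(ann, file.path(audio_dir, "annotations.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}

#' Read a call table written by [write_call_table()]
#'
#' @param path CSV path; leading `#` comment lines are skipped.
#' @return Data frame of calls.
#' @export
read_call_table <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
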