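#' Detect call boundaries from the amplitude envelope
#'
#' Segments a mono waveform into calls: the RMS envelope (moving average of
#' the squared signal over `smooth_s`) is compared with
#' `threshold_fraction * max(envelope)`; contiguous supra-threshold runs are
#' merged across gaps shorter than `min_gap` and runs shorter than
#' `min_duration` are discarded.
#'
#' @param samples Numeric mono waveform.
#' @param sample_rate Sampling rate in Hz.
#' @param threshold_fraction Fraction of the envelope maximum, in (0, 1).
#' @param min_duration Minimum call length in seconds (default 0.03).
#' @param min_gap Gaps shorter than this (s) are bridged (default 0.05).
#' @param smooth_s Envelope smoothing window in seconds (default 0.005).
#' @return Data frame with columns `start`, `end` (seconds, half-open
#'   `[start, end)`), non-overlapping and sorted; zero rows for silence.
#' @export
detect_call_boundaries <- function(samples, sample_rate,
                                   threshold_fraction = 0.1,
                                   min_duration = 0.03,
                                   min_gap = 0.05,
                                   smooth_s = 0.005) {
  if (any(!is.finite(samples))) stop("waveform contains non-finite samples")
  stopifnot(threshold_fraction > 0, threshold_fraction < 1)
  empty <- data.frame(start = numeric(0), end = numeric(0))
  if (length(samples) == 0L || all(samples == 0)) return(empty)

  w <- max(1L, round(smooth_s * sample_rate))
  env <- sqrt(stats::filter(samples^2, rep(1 / w, w), sides = 2))
  env[is.na(env)] <- 0
  above <- env >= threshold_fraction * max(env)

  r <- rle(as.vector(above))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- cbind(starts[r$values], ends[r$values])
  if (nrow(seg) == 0L) return(empty)

  # bridge short gaps
  gap_samp <- min_gap * sample_rate
  merged <- seg[1, , drop = FALSE]
  if (nrow(seg) > 1) for (i in 2:nrow(seg)) {
    if (seg[i, 1] - merged[nrow(merged), 2] - 1 < gap_samp) {
      merged[nrow(merged), 2] <- seg[i, 2]
    } else {
      merged <- rbind(merged, seg[i, ])
    }
  }
  out <- data.frame(start = (merged[, 1] - 1) / sample_rate,
                    end = merged[, 2] / sample_rate)
  out <- out[out$end - out$start >= min_duration, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract the eight acoustic descriptors from one call
#'
#' Frames the segment with a Hann window (default 512 samples, 1 ms step),
#' computes per-frame power spectra (DC bin excluded), and derives:
#' `duration` (segment length), `mean_amplitude` (mean per-frame RMS of the
#' unwindowed signal), spectral energy quantiles `q25`/`q50`/`q75`
#' (frequencies below which 25/50/75% of cumulative spectral energy lies),
#' `spectral_centroid` (energy-weighted mean frequency), `peak_frequency`
#' (maximum of the frame-averaged power spectrum) and `spectral_slope`
#' (slope of a linear regression of the frame-averaged spectrum level in dB
#' on frequency in kHz).
#'
#' @param samples Numeric mono waveform of one segmented call.
#' @param sample_rate Sampling rate in Hz.
#' @param frame_length Analysis window length in samples (default 512).
#' @param step Frame step in seconds (default 0.001).
#' @param quantile_mode `"per_frame"` (default): quantiles and centroid are
#'   computed per frame then averaged over frames with non-zero energy;
#'   `"mean_spectrum"`: computed once on the frame-averaged spectrum.
#' @return Named numeric vector of class `acoustic_parameters` with the 8
#'   descriptors in canonical order.
#' @export
extract_features <- function(samples, sample_rate,
                             frame_length = 512, step = 0.001,
                             quantile_mode = c("per_frame", "mean_spectrum")) {
  quantile_mode <- match.arg(quantile_mode)
  if (any(!is.finite(samples))) stop("waveform contains non-finite samples")
  if (step <= 0) stop("step must be positive")
  n <- length(samples)
  if (n < frame_length) stop("segment shorter than one analysis frame")
  if (all(samples == 0)) stop("silent segment: spectrum undefined")

  hop <- max(1L, round(step * sample_rate))
  starts <- seq(1L, n - frame_length + 1L, by = hop)
  win <- 0.5 * (1 - cos(2 * pi * seq_len(frame_length) / (frame_length + 1)))
  nb <- frame_length %/% 2              # bins 1..nb, DC excluded
  freqs <- seq_len(nb) * sample_rate / frame_length

  frames <- matrix(samples[outer(seq_len(frame_length) - 1L, starts, "+")],
                   nrow = frame_length)
  rms <- sqrt(colMeans(frames^2))
  P <- Mod(stats::mvfft(frames * win))[2:(nb + 1L), , drop = FALSE]^2
  tot <- colSums(P)
  use <- tot > 0

  frame_quant <- function(p, probs) {
    cum <- cumsum(p)
    sapply(probs, function(q) freqs[which(cum >= q * cum[length(cum)])[1]])
  }
  if (quantile_mode == "per_frame") {
    qs <- apply(P[, use, drop = FALSE], 2, frame_quant,
                probs = c(0.25, 0.5, 0.75))
    quant <- rowMeans(qs)
    centroid <- mean(colSums(P[, use, drop = FALSE] * freqs) / tot[use])
  } else {
    mp <- rowMeans(P)
    quant <- frame_quant(mp, c(0.25, 0.5, 0.75))
    centroid <- sum(mp * freqs) / sum(mp)
  }

  mean_spec <- rowMeans(P)
  peak <- freqs[which.max(mean_spec)]
  pos <- mean_spec > 0
  level_db <- 10 * log10(mean_spec[pos] / max(mean_spec))
  slope <- unname(stats::coef(stats::lm(level_db ~ I(freqs[pos] / 1000)))[2])

  out <- c(duration = n / sample_rate,
           mean_amplitude = mean(rms),
           peak_frequency = peak,
           q25 = quant[1], q50 = quant[2], q75 = quant[3],
           spectral_centroid = centroid,
           spectral_slope = slope)
  names(out) <- acoustic_parameter_names()
  class(out) <- "acoustic_parameters"
  out
}

#' Segment and extract features from annotated WAV files
#'
#' For each annotation row, reads the WAV file, detects the call (or uses the
#' whole file when segmentation finds nothing longer than the minimum), and
#' extracts the eight descriptors. One feature row is produced per annotation
#' using the longest detected segment (the annotated call).
#'
#' @param wav_dir Directory of WAV files.
#' @param annotations Data frame with at least a `file` column; remaining
#'   columns (e.g. `call_id`, `individual`, `context`, `age_days`) are
#'   carried through.
#' @param channel Channel to analyse (default 1).
#' @param ... Passed to [detect_call_boundaries()] and [extract_features()].
#' @return Data frame: annotation columns plus the 8 feature columns.
#' @export
extract_features_table <- function(wav_dir, annotations, channel = 1L, ...) {
  stopifnot(is.data.frame(annotations), "file" %in% names(annotations))
  dots <- list(...)
  seg_args <- dots[names(dots) %in%
                     names(formals(detect_call_boundaries))]
  feat_args <- dots[names(dots) %in% names(formals(extract_features))]
  rows <- lapply(seq_len(nrow(annotations)), function(i) {
    w <- read_wav(file.path(wav_dir, annotations$file[i]), channel = channel)
    segs <- do.call(detect_call_boundaries,
                    c(list(w$samples, w$sample_rate), seg_args))
    if (nrow(segs) == 0L) {
      seg <- c(0, length(w$samples) / w$sample_rate)
    } else {
      k <- which.max(segs$end - segs$start)
      seg <- c(segs$start[k], segs$end[k])
    }
    i0 <- max(1L, floor(seg[1] * w$sample_rate) + 1L)
    i1 <- min(length(w$samples), ceiling(seg[2] * w$sample_rate))
    feats <- do.call(extract_features,
                     c(list(w$samples[i0:i1], w$sample_rate), feat_args))
    as.data.frame(as.list(unclass(feats)))
  })
  cbind(annotations, do.call(rbind, rows))
}
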