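#' Zero-phase 1--100 Hz band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth filtering, applied as a
#' high-pass at 1 Hz (order 4) cascaded with a low-pass at 100 Hz
#' (order 8). The cascade attenuates by at least 20 dB at 0.5 Hz and at
#' 120 Hz while leaving passband amplitudes within a few percent. Signal
#' length is unchanged.
#'
#' @param ts a [parcel_ts()].
#' @return the filtered [parcel_ts()].
#' @export
bandpass_1_100 <- function(ts) {
  stopifnot(inherits(ts, "parcel_ts"))
  fs <- ts$sampling_rate
  if (fs / 2 <= 100)
    stop("Nyquist must exceed 100 Hz (sampling_rate > 200 Hz)")
  hp <- signal::butter(4, 1 / (fs / 2), type = "high")
  lp <- signal::butter(8, 100 / (fs / 2), type = "low")
  vals <- t(apply(ts$values, 1, function(x)
    signal::filtfilt(lp, signal::filtfilt(hp, x))))
  parcel_ts(vals, fs, ts$state_labels, ts$participant_id, ts$region_labels)
}

#' Binarize an epoch around its mean
#'
#' The epoch is linearly detrended (least squares) and each sample coded
#' 1 where it strictly exceeds the post-detrend mean, else 0. Values
#' exactly at the threshold map to 0 (fixed tie rule), so a constant
#' epoch yields the all-zero sequence.
#'
#' @param v numeric sample vector (length >= 2).
#' @param detrend apply the linear detrend (default TRUE); FALSE
#'   thresholds the raw values at their mean.
#' @return integer 0/1 vector.
#' @export
binarize_epoch <- function(v, detrend = TRUE) {
  n <- length(v)
  if (n < 2) stop("epoch must have at least 2 samples")
  if (detrend) {
    t0 <- seq_len(n) - (n + 1) / 2          # centered time axis
    v <- v - mean(v) - t0 * sum(t0 * v) / sum(t0^2)
  }
  as.integer(v > mean(v))
}

#' LZ76 phrase count
#'
#' Number of phrases in the Lempel-Ziv (1976) exhaustive-history parse
#' of a binary sequence, computed by Kaspar-Schuster production
#' counting. Deterministic; grows like `T / log2(T)` for an iid
#' fair-coin sequence and stays at 2 for any constant sequence of
#' length >= 2.
#'
#' @param seq 0/1 vector (length >= 1).
#' @return integer phrase count.
#' @export
lz76_count <- function(seq) {
  if (length(seq) == 0) stop("empty sequence")
  lz76_count_cpp(as.integer(seq))
}

#' Normalized Lempel-Ziv complexity of an epoch
#'
#' The epoch is binarized (see [binarize_epoch()]) and the LZ76 phrase
#' count divided by `T / log2(T)`, so a fully predictable signal scores
#' near 0 (exactly `2 log2(T) / T` for a constant epoch) and a fully
#' random signal scores near 1.
#'
#' @inheritParams binarize_epoch
#' @return list with `raw_count` and `normalized`.
#' @export
normalized_lzc <- function(v, detrend = TRUE) {
  b <- binarize_epoch(v, detrend = detrend)
  T <- length(b)
  cnt <- lz76_count(b)
  list(raw_count = cnt, normalized = cnt / (T / log2(T)))
}

#' Lempel-Ziv complexity feature table of a session
#'
#' Band-passes the series at 1--100 Hz, cuts non-overlapping 4 s epochs
#' within state segments (4 s being the minimum length at which the
#' normalized complexity is reliably estimated at these sampling rates),
#' and computes per-region normalized LZc. Columns are `lzc__<region>`.
#'
#' @param ts a [parcel_ts()].
#' @param epoch_s epoch length in seconds (default 4).
#' @param filter apply [bandpass_1_100()] first (default TRUE).
#' @return a [feature_table()].
#' @export
lzc_feature_table <- function(ts, epoch_s = 4, filter = TRUE) {
  stopifnot(inherits(ts, "parcel_ts"))
  if (filter) ts <- bandpass_1_100(ts)
  eps <- epoch_series(ts, epoch_s)
  regions <- ts$region_labels
  feats <- do.call(rbind, lapply(eps, function(ep) {
    vapply(seq_len(nrow(ep$values)), function(r)
      normalized_lzc(ep$values[r, ])$normalized, 0)
  }))
  colnames(feats) <- paste0("lzc__", regions)
  df <- data.frame(participant = ts$participant_id,
                   state = vapply(eps, `[[`, "", "state"),
                   epoch_idx = vapply(eps, `[[`, 0L, "epoch_idx"),
                   stringsAsFactors = FALSE)
  feature_table(cbind(df, as.data.frame(feats)))
}
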