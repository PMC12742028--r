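#' Cut a parcel time series into state-pure epochs
#'
#' Non-overlapping contiguous windows are cut within each contiguous
#' state segment; a partial trailing window is discarded, and a segment
#' shorter than the epoch length contributes zero epochs. Epochs are
#' numbered by a strictly increasing chronological index over the whole
#' recording.
#'
#' @param ts a [parcel_ts()].
#' @param length_s epoch length in seconds.
#' @return list of epochs, each `list(values = region x sample matrix,
#'   state, epoch_idx)`.
#' @export
epoch_series <- function(ts, length_s = 1) {
  stopifnot(inherits(ts, "parcel_ts"), length_s > 0)
  fs <- ts$sampling_rate
  len <- round(length_s * fs)
  r <- rle(ts$state_labels)
  seg_ends <- cumsum(r$lengths)
  seg_starts <- c(1, head(seg_ends, -1) + 1)
  out <- list()
  idx <- 0L
  for (s in seq_along(r$values)) {
    n_ep <- r$lengths[s] %/% len
    if (n_ep == 0) next
    for (e in seq_len(n_ep)) {
      idx <- idx + 1L
      a <- seg_starts[s] + (e - 1L) * len
      out[[idx]] <- list(values = ts$values[, a:(a + len - 1L), drop = FALSE],
                         state = r$values[s], epoch_idx = idx)
    }
  }
  out
}

#' One-sided Hanning-tapered power spectrum of a 1 s epoch
#'
#' The epoch must be exactly one second long so the discrete Fourier
#' transform natively yields 1 Hz bins. Power is scaled so that the sum
#' over all one-sided bins equals the taper-compensated signal variance
#' (Parseval-consistent): `P_k = 2 |X_k|^2 / (N * sum(w^2))` with `w` the
#' Hanning taper.
#'
#' @param epoch region x sample matrix (one row per region).
#' @param sampling_rate Hz; must equal `ncol(epoch)`.
#' @param fmax highest frequency bin returned (default 90 Hz).
#' @return `psd_estimate`: list with `frequencies` (1..fmax Hz) and
#'   `power` (region x frequency matrix).
#' @export
psd_hanning <- function(epoch, sampling_rate, fmax = 90) {
  if (is.vector(epoch)) epoch <- matrix(epoch, nrow = 1)
  n <- ncol(epoch)
  if (n != round(sampling_rate))
    stop("psd_hanning requires 1 s epochs (", round(sampling_rate),
         " samples at ", sampling_rate, " Hz); re-epoch the data")
  if (fmax >= n / 2) stop("fmax must be below Nyquist")
  k <- seq_len(n) - 1
  w <- 0.5 * (1 - cos(2 * pi * k / (n - 1)))
  X <- stats::mvfft(t(epoch * rep(w, each = nrow(epoch))))
  P <- 2 * Mod(X)^2 / (n * sum(w^2))
  freqs <- seq_len(fmax)
  structure(list(frequencies = freqs,
                 power = t(P[freqs + 1, , drop = FALSE])),
            class = "psd_estimate")
}

#' Fit the aperiodic (1/f) component of a power spectrum
#'
#' Robust line fit of log10(power) on log10(frequency): an ordinary
#' least-squares fit, followed by a single re-fit that excludes bins
#' whose residual exceeds 2.5 median-absolute-deviations *above* the
#' first fit (one-sided rejection of oscillatory peaks), each rejected
#' peak widened by two bins per side to cover the spectral leakage of
#' the 1 s Hanning taper. The aperiodic
#' exponent is the negative slope; the model is
#' `log10 P(f) = offset - exponent * log10 f`.
#'
#' @param psd a `psd_estimate` (from [psd_hanning()]), or a region x
#'   frequency power matrix with an accompanying `frequencies` vector.
#' @param fit_range numeric length-2 Hz interval (default `c(1, 90)`).
#' @param frequencies needed only when `psd` is a bare matrix.
#' @return `aperiodic_fit`: list with per-region `offset`, `exponent`,
#'   and `fit_range`.
#' @export
fit_aperiodic <- function(psd, fit_range = c(1, 90), frequencies = NULL) {
  if (inherits(psd, "psd_estimate")) {
    P <- psd$power; frequencies <- psd$frequencies
  } else P <- psd
  if (is.vector(P)) P <- matrix(P, nrow = 1)
  sel <- frequencies >= fit_range[1] & frequencies <= fit_range[2]
  if (sum(sel) < 5) stop("fewer than 5 bins in fit range")
  if (any(P[, sel] <= 0)) stop("power must be strictly positive on the fit range")
  x <- log10(frequencies[sel])
  Y <- t(log10(P[, sel, drop = FALSE]))     # bins x regions
  fit_w <- function(W) {
    sw <- colSums(W)
    mx <- colSums(W * x) / sw
    my <- colSums(W * Y) / sw
    sxx <- colSums(W * x^2) - sw * mx^2
    sxy <- colSums(W * x * Y) - sw * mx * my
    slope <- sxy / sxx
    list(slope = slope, intercept = my - slope * mx)
  }
  W <- matrix(1, nrow(Y), ncol(Y))
  f1 <- fit_w(W)
  resid <- Y - (rep(1, nrow(Y)) %o% f1$intercept + x %o% f1$slope)
  md <- apply(resid, 2, mad)
  W2 <- W
  m <- nrow(Y)
  for (j in seq_len(ncol(Y))) {
    if (md[j] > 0) {
      drop <- resid[, j] > 2.5 * md[j]
      # widen each rejected peak by 2 bins per side: the 1 s Hanning
      # taper leaks oscillatory power into neighbouring bins
      if (any(drop)) {
        core <- which(drop)
        drop[pmax(1, pmin(m, rep(core, each = 5) + (-2:2)))] <- TRUE
      }
      if (sum(!drop) >= 5) W2[drop, j] <- 0
    }
  }
  f2 <- fit_w(W2)
  structure(list(offset = unname(f2$intercept),
                 exponent = unname(-f2$slope),
                 fit_range = fit_range),
            class = "aperiodic_fit")
}

#' Frequency band definitions
#'
#' A band covers the integer-Hz bins `low <= f <= high`. The default set
#' uses canonical bounds — delta 1--4, theta 4--8, alpha 8--13, beta
#' 13--30, low gamma 30--60, high gamma 60--90 — plus a narrow `beta27`
#' band (25--29 Hz) around the 27 Hz beta component of interest. All
#' bounds are configuration, not measurement.
#'
#' @param name band name.
#' @param low,high Hz bounds, `1 <= low < high <= 90`.
#' @return a `band_definition` / named list of them.
#' @export
band_definition <- function(name, low, high) {
  if (!(low >= 1 && low < high && high <= 90))
    stop("band bounds must satisfy 1 <= low < high <= 90")
  structure(list(name = name, low = low, high = high),
            class = "band_definition")
}

#' @rdname band_definition
#' @export
default_bands <- function() {
  specs <- list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
                beta = c(13, 30), gamma_low = c(30, 60),
                gamma_high = c(60, 90), beta27 = c(25, 29))
  lapply(stats::setNames(names(specs), names(specs)),
         function(nm) band_definition(nm, specs[[nm]][1], specs[[nm]][2]))
}

#' Aperiodic-corrected band power
#'
#' Mean over the band's integer bins of `log10(power) - log10(aperiodic
#' model)` — the periodic residual in log10-power space. May be negative
#' when power falls below the aperiodic trend. Invariant to overall
#' signal gain (a gain shifts both terms equally).
#'
#' @param psd a `psd_estimate`.
#' @param fit an `aperiodic_fit` for the same regions.
#' @param band a [band_definition()].
#' @param correct subtract the aperiodic model (default TRUE); with
#'   FALSE, returns plain mean log10 band power.
#' @return per-region numeric vector.
#' @export
corrected_band_power <- function(psd, fit, band, correct = TRUE) {
  sel <- psd$frequencies >= band$low & psd$frequencies <= band$high
  if (!any(sel)) stop("empty band: no bins in [", band$low, ", ", band$high, "]")
  lf <- log10(psd$frequencies[sel])
  lp <- log10(psd$power[, sel, drop = FALSE])
  if (!correct) return(rowMeans(lp))
  model <- fit$offset %o% rep(1, sum(sel)) - fit$exponent %o% lf
  rowMeans(lp - model)
}

#' Spectral feature table of a session
#'
#' One row per 1 s epoch: per band one aperiodic-corrected band-power
#' column per region, plus one aperiodic-exponent column per region
#' (`aperiodic__<region>`), with participant/state/chronology metadata.
#'
#' @param ts a [parcel_ts()].
#' @param bands named list of [band_definition()] (default
#'   [default_bands()]); an empty list yields an exponent-only table.
#' @param fit_range aperiodic fit range in Hz.
#' @param correct aperiodic-correct the band power (default TRUE).
#' @return a [feature_table()].
#' @export
spectral_feature_table <- function(ts, bands = default_bands(),
                                   fit_range = c(1, 90), correct = TRUE) {
  stopifnot(inherits(ts, "parcel_ts"))
  eps <- epoch_series(ts, 1)
  regions <- ts$region_labels
  feat_rows <- lapply(eps, function(ep) {
    psd <- psd_hanning(ep$values, ts$sampling_rate)
    fit <- fit_aperiodic(psd, fit_range)
    c(unlist(unname(lapply(bands, function(b)
        stats::setNames(corrected_band_power(psd, fit, b, correct = correct),
                        paste0(b$name, "__", regions))))),
      stats::setNames(fit$exponent, paste0("aperiodic__", regions)))
  })
  feats <- do.call(rbind, feat_rows)
  df <- data.frame(participant = ts$participant_id,
                   state = vapply(eps, `[[`, "", "state"),
                   epoch_idx = vapply(eps, `[[`, 0L, "epoch_idx"),
                   stringsAsFactors = FALSE)
  feature_table(cbind(df, as.data.frame(feats)))
}
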