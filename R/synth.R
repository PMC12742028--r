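#' Parcellated time-series container
#'
#' Region x sample signal matrix with per-sample state labels. The unit
#' of analysis downstream is the epoch; state segments are generated and
#' labelled contiguously so epochs never straddle a state boundary.
#'
#' @param values region x sample numeric matrix.
#' @param sampling_rate Hz.
#' @param state_labels character vector, one state per sample.
#' @param participant_id opaque identifier.
#' @param region_labels unique region names, one per row of `values`.
#' @return A `parcel_ts` object.
#' @export
parcel_ts <- function(values, sampling_rate, state_labels,
                      participant_id = "P01", region_labels = NULL) {
  if (!is.matrix(values) || anyNA(values))
    stop("values must be a complete numeric matrix (region x sample)")
  if (length(state_labels) != ncol(values))
    stop("state_labels must have one entry per sample")
  if (!all(state_labels %in% STATES))
    stop("unknown state label(s): ",
         paste(unique(setdiff(state_labels, STATES)), collapse = ", "))
  if (is.null(region_labels))
    region_labels <- rownames(values) %||% sprintf("region_%03d", seq_len(nrow(values)))
  if (length(region_labels) != nrow(values) || anyDuplicated(region_labels))
    stop("region_labels must be unique, one per region")
  rownames(values) <- region_labels
  structure(list(values = values, sampling_rate = sampling_rate,
                 state_labels = as.character(state_labels),
                 participant_id = as.character(participant_id),
                 region_labels = region_labels),
            class = "parcel_ts")
}

#' @export
print.parcel_ts <- function(x, ...) {
  cat(sprintf("<parcel_ts> participant %s: %d regions x %d samples @ %g Hz\n",
              x$participant_id, nrow(x$values), ncol(x$values),
              x$sampling_rate))
  cat("state totals (s):",
      paste(sprintf("%s=%g", names(table(x$state_labels)),
                    table(x$state_labels) / x$sampling_rate), collapse = "  "),
      "\n")
  invisible(x)
}

# narrowband Gaussian noise via FFT masking, unit SD, one column per region
band_noise <- function(n, R, low, high, fs) {
  w <- matrix(rnorm(n * R), n, R)
  W <- stats::mvfft(w)
  f <- pmin(seq_len(n) - 1, n - (seq_len(n) - 1)) * fs / n
  keep <- f >= low & f <= high
  W[!keep, ] <- 0
  x <- Re(stats::mvfft(W, inverse = TRUE)) / n
  scale(x, center = FALSE, scale = apply(x, 2, sd))
}

# 1/f-shaped Gaussian noise: spectral amplitudes scaled by f^(-chi/2),
# one exponent per column; unit SD per column. Power below 1 Hz is
# removed: the emulated pipeline is band-limited at 1 Hz and sub-Hz 1/f
# power would otherwise leak into the lowest analysis bins of short
# tapered epochs and bias the aperiodic fit.
onef_noise <- function(n, chi, fs) {
  R <- length(chi)
  w <- matrix(rnorm(n * R), n, R)
  W <- stats::mvfft(w)
  f <- pmin(seq_len(n) - 1, n - (seq_len(n) - 1)) * fs / n
  amp <- outer(f, chi, function(fi, ci) ifelse(fi >= 1, fi^(-ci / 2), 0))
  x <- Re(stats::mvfft(W * amp, inverse = TRUE)) / n
  scale(x, center = FALSE, scale = apply(x, 2, sd))
}

#' Generate one synthetic session
#'
#' Simulates a parcel-level MEG-like recording following a session
#' protocol. Per state segment and region the signal is the sum of
#' 1/f-shaped background noise (exponent chi from the effect spec),
#' band-limited alpha (8--12 Hz) and beta (25--29 Hz) oscillations — the
#' beta amplitude scaled by the planted state multiplier — blended with
#' broadband white noise according to the complexity drive, then mixed
#' across regions by the mixing matrix. Segments are generated
#' independently, so no filter transient crosses a state boundary.
#'
#' @param protocol a [session_protocol()].
#' @param effects an [effect_spec()].
#' @param seed integer; the same seed reproduces the session exactly.
#' @param participant_id identifier stored in the result.
#' @return A [parcel_ts()].
#' @export
generate_session <- function(protocol, effects, seed,
                             participant_id = "P01") {
  stopifnot(inherits(protocol, "session_protocol"),
            inherits(effects, "effect_spec"))
  fs <- attr(protocol, "sampling_rate")
  if (fs < 200)
    stop("invalid protocol: sampling_rate must be >= 200 Hz ",
         "(the 1-100 Hz analysis band must lie below Nyquist)")
  set.seed(as.integer(seed))
  R <- effects$region_count
  segs <- vector("list", nrow(protocol))
  labels <- vector("list", nrow(protocol))
  # structured-component scale used to weight the white-noise blend
  c0 <- sqrt(1 + effects$alpha_amp^2 + effects$beta_base^2)
  for (i in seq_len(nrow(protocol))) {
    st <- protocol$state[i]
    n <- protocol$duration_s[i] * fs
    chi <- effects$exponent[st, ]
    bg <- onef_noise(n, chi, fs)
    al <- band_noise(n, R, 8, 12, fs)
    be <- band_noise(n, R, 25, 29, fs)
    bmul <- effects$beta_base * effects$beta_amp[st, ]
    structured <- bg + effects$alpha_amp * al +
      sweep(be, 2, bmul, `*`)
    w <- effects$complexity[st, ]
    wh <- matrix(rnorm(n * R), n, R)
    x <- sweep(structured, 2, 1 - w, `*`) + sweep(wh, 2, w * c0, `*`)
    x <- x %*% t(effects$cross_region_mixing)
    segs[[i]] <- x * effects$noise_sd
    labels[[i]] <- rep(st, n)
  }
  parcel_ts(t(do.call(rbind, segs)), fs, unlist(labels),
            participant_id = participant_id,
            region_labels = effects$region_labels)
}

#' Generate a cohort of synthetic participants
#'
#' Each participant's effect parameters are drawn around the cohort-level
#' effect spec: per region, the log beta multiplier gets a normal
#' perturbation with SD `between_participant_sd`, the complexity drive an
#' additive perturbation with SD `between_participant_sd / 5` (clamped to
#' `[0, 1]`) and the aperiodic exponent an additive perturbation with SD
#' `between_participant_sd / 2` (floored at 0.1). Perturbations are
#' shared across states within a participant, so they shift that
#' participant's feature distributions without altering the planted state
#' contrast — the mechanism by which across-participant generalization
#' degrades while within-participant decoding is untouched.
#'
#' @param n_participants number of participants (>= 2).
#' @param effects cohort-level [effect_spec()].
#' @param between_participant_sd dimensionless spread (0 = identical
#'   participants). Default 0.3.
#' @param seed integer master seed.
#' @param protocol a [session_protocol()]; default [default_protocol()].
#' @return list of [parcel_ts()], one per participant, ids `P01`, `P02`, ...
#' @export
generate_cohort <- function(n_participants, effects,
                            between_participant_sd = 0.3, seed = 1,
                            protocol = default_protocol()) {
  pars <- cohort_params(n_participants, effects, between_participant_sd, seed)
  lapply(seq_len(n_participants), function(p)
    generate_session(protocol, pars$effects[[p]], seed = pars$seeds[p],
                     participant_id = pars$ids[p]))
}

# draw per-participant effect specs and session seeds; shared by
# generate_cohort and the pipeline driver (which streams participants to
# bound memory)
cohort_params <- function(n_participants, effects, between_participant_sd,
                          seed) {
  if (n_participants < 2)
    stop("n_participants must be >= 2 (across-participant split undefined)")
  set.seed(as.integer(seed))
  R <- effects$region_count
  session_seeds <- sample.int(.Machine$integer.max - 1L, n_participants)
  eff_list <- lapply(seq_len(n_participants), function(p) {
    jb <- exp(rnorm(R, 0, between_participant_sd))
    jc <- rnorm(R, 0, between_participant_sd / 5)
    jx <- rnorm(R, 0, between_participant_sd / 2)
    eff <- effects
    eff$beta_amp <- sweep(eff$beta_amp, 2, jb, `*`)
    eff$complexity <- pmin(pmax(sweep(eff$complexity, 2, jc, `+`), 0), 1)
    eff$exponent <- pmax(sweep(eff$exponent, 2, jx, `+`), 0.1)
    eff
  })
  list(effects = eff_list, seeds = session_seeds,
       ids = sprintf("P%02d", seq_len(n_participants)))
}

#' Per-segment manifest of a session
#'
#' @param ts a [parcel_ts()].
#' @return data frame with participant, state, start_s, end_s per
#'   contiguous state segment.
#' @export
session_manifest <- function(ts) {
  r <- rle(ts$state_labels)
  ends <- cumsum(r$lengths) / ts$sampling_rate
  data.frame(participant = ts$participant_id, state = r$values,
             start_s = c(0, head(ends, -1)), end_s = ends,
             stringsAsFactors = FALSE)
}

#' Save / load a session
#'
#' The signal matrix is stored as an Arrow Feather table (one column per
#' region), alongside a JSON sidecar (sampling rate, participant, region
#' labels, per-sample state labels run-length encoded) and a TSV segment
#' manifest.
#'
#' @param ts a [parcel_ts()].
#' @param dir output directory (created if needed).
#' @return `save_session` returns the directory invisibly; `load_session`
#'   returns the [parcel_ts()].
#' @export
save_session <- function(ts, dir) {
  if (!requireNamespace("arrow", quietly = TRUE))
    stop("the 'arrow' package is required for session persistence")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  df <- as.data.frame(t(ts$values))
  names(df) <- ts$region_labels
  arrow::write_feather(df, file.path(dir, "values.feather"))
  r <- rle(ts$state_labels)
  jsonlite::write_json(
    list(sampling_rate = ts$sampling_rate,
         participant_id = ts$participant_id,
         region_labels = ts$region_labels,
         state_rle = list(lengths = r$lengths, values = r$values)),
    file.path(dir, "session.json"), auto_unbox = TRUE, digits = NA)
  write.table(session_manifest(ts), file.path(dir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname save_session
#' @export
load_session <- function(dir) {
  if (!requireNamespace("arrow", quietly = TRUE))
    stop("the 'arrow' package is required for session persistence")
  meta <- jsonlite::read_json(file.path(dir, "session.json"),
                              simplifyVector = TRUE)
  df <- arrow::read_feather(file.path(dir, "values.feather"))
  parcel_ts(t(as.matrix(df)), meta$sampling_rate,
            inverse.rle(structure(meta$state_rle, class = "rle")),
            participant_id = meta$participant_id,
            region_labels = meta$region_labels)
}
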