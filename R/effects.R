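#' Planted state effects for the synthetic generator
#'
#' An `effect_spec` collects, per region and per state, the parameters of
#' the simulated signal model:
#'
#' * `beta_amp` — multiplicative factor on the amplitude of the ~27 Hz
#'   (25--29 Hz) beta oscillation. Values below 1 plant the beta-power
#'   reduction characteristic of self-boundary dissolution.
#' * `exponent` — the aperiodic 1/f exponent chi of the broadband
#'   background (power ~ f^-chi).
#' * `complexity` — mixing weight in `[0, 1]` of broadband white noise
#'   versus the structured (1/f + oscillatory) component. Raising it
#'   provably raises the expected normalized Lempel-Ziv complexity, so it
#'   is the monotone handle for planting complexity effects.
#'
#' plus region-independent plumbing: the cross-region mixing matrix
#' (rows normalized to unit sum) and the baseline noise SD.
#'
#' Each per-state argument may be a single value (shared by all regions),
#' a length-`region_count` vector, or a state-by-region matrix with
#' rownames `rest`, `SBminus`, `SBplus`.
#'
#' @param region_count number of regions (default 62, the merged-atlas
#'   cardinality).
#' @param beta_amp beta amplitude multipliers (> 0); scalar, vector or
#'   3 x region matrix. Default 1 (no effect).
#' @param exponent aperiodic exponents chi; default 1.5.
#' @param complexity white-noise mixing weights in `[0,1]`; default 0.3.
#' @param alpha_amp relative amplitude of the 8--12 Hz alpha oscillation
#'   (scalar, shared across states/regions). Default 0.6.
#' @param beta_base relative base amplitude of the 25--29 Hz beta
#'   oscillation before the state multiplier. Default 0.5.
#' @param cross_region_mixing region x region mixing matrix; rows are
#'   renormalized to unit sum. Default: mild uniform mixing with weight
#'   0.2 spread over all regions.
#' @param noise_sd baseline amplitude scale. Default 1.
#' @param region_labels optional region names; default the packaged
#'   62-region merged-atlas labels when `region_count == 62`, else
#'   `region_001` ...
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(region_count = 62,
                        beta_amp = 1,
                        exponent = 1.5,
                        complexity = 0.3,
                        alpha_amp = 0.6,
                        beta_base = 0.5,
                        cross_region_mixing = NULL,
                        noise_sd = 1,
                        region_labels = NULL) {
  R <- as.integer(region_count)
  if (R < 1) stop("region_count must be >= 1")
  expand <- function(x, what) {
    if (is.matrix(x)) {
      if (is.null(rownames(x)) || !all(STATES %in% rownames(x)) || ncol(x) != R)
        stop(what, ": matrix must have rows rest/SBminus/SBplus and ", R, " columns")
      return(x[STATES, , drop = FALSE])
    }
    if (length(x) == 1) x <- rep(x, R)
    if (length(x) != R) stop(what, ": expected scalar, length-", R,
                             " vector, or state x region matrix")
    matrix(rep(x, each = 3), nrow = 3, dimnames = list(STATES, NULL))
  }
  beta_amp <- expand(beta_amp, "beta_amp")
  exponent <- expand(exponent, "exponent")
  complexity <- expand(complexity, "complexity")
  if (any(beta_amp <= 0)) stop("beta_amp multipliers must be > 0")
  if (any(complexity < 0 | complexity > 1)) stop("complexity must lie in [0, 1]")
  if (is.null(cross_region_mixing)) {
    m <- 0.2
    cross_region_mixing <- matrix(m / R, R, R)
    diag(cross_region_mixing) <- diag(cross_region_mixing) + (1 - m)
  }
  if (!is.matrix(cross_region_mixing) || any(dim(cross_region_mixing) != R))
    stop("cross_region_mixing must be a ", R, " x ", R, " matrix")
  rs <- rowSums(cross_region_mixing)
  if (any(rs <= 0)) stop("cross_region_mixing rows must have positive sums")
  cross_region_mixing <- cross_region_mixing / rs
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (is.null(region_labels)) {
    region_labels <- if (R == 62) atlas_region_labels() else
      sprintf("region_%03d", seq_len(R))
  }
  if (length(region_labels) != R || anyDuplicated(region_labels))
    stop("region_labels must be ", R, " unique names")
  structure(list(region_count = R, beta_amp = beta_amp, exponent = exponent,
                 complexity = complexity, alpha_amp = alpha_amp,
                 beta_base = beta_base,
                 cross_region_mixing = cross_region_mixing,
                 noise_sd = noise_sd, region_labels = region_labels),
            class = "effect_spec")
}

#' Preset effect specs
#'
#' `effect_preset("null")` plants no state differences. The
#' `"small_to_medium"` preset plants the qualitative effect pattern of
#' self-boundary dissolution — beta-band power reduced and broadband
#' complexity raised in SBminus relative to rest, with SBplus
#' intermediate — at magnitudes calibrated so that region-wise Cohen's d
#' on the LZc features falls in the small-to-medium band (|d| ~ 0.2-0.4).
#' `"strong"` plants a clearly separable effect for sanity runs.
#'
#' @param name one of `"null"`, `"small_to_medium"`, `"strong"`.
#' @param region_count number of regions.
#' @param ... passed on to [effect_spec()].
#' @return An [effect_spec()].
#' @export
effect_preset <- function(name = c("null", "small_to_medium", "strong"),
                          region_count = 62, ...) {
  name <- match.arg(name)
  R <- region_count
  st_mat <- function(rest, sbm, sbp)
    matrix(rep(c(rest, sbm, sbp), R), nrow = 3,
           dimnames = list(STATES, NULL))
  switch(name,
    null = effect_spec(region_count = R, ...),
    small_to_medium = effect_spec(
      region_count = R,
      beta_amp = st_mat(1.0, 0.90, 0.97),
      complexity = st_mat(0.300, 0.3135, 0.305),
      exponent = st_mat(1.50, 1.47, 1.49), ...),
    strong = effect_spec(
      region_count = R,
      beta_amp = st_mat(1.0, 0.3, 0.9),
      complexity = st_mat(0.2, 0.55, 0.25),
      exponent = st_mat(1.6, 1.3, 1.5), ...))
}
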