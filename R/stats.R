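#' Grand-mean threshold classifier accuracy
#'
#' Univariate benchmark: the decision boundary is the mean of all
#' observations pooled across both classes, with an a priori direction —
#' `low_is_positive` predicts the positive class below the boundary (the
#' working hypothesis for oscillatory power in self-boundary
#' dissolution), `high_is_positive` above it (the hypothesis for LZc).
#' Observations exactly at the boundary earn half credit, so degenerate
#' zero-variance data score 0.5 by construction.
#'
#' @param positive,negative observation vectors of the two classes.
#' @param direction `"low_is_positive"` or `"high_is_positive"`.
#' @param boundary optional override of the pooled grand mean.
#' @return fraction correct over all observations.
#' @export
univariate_threshold_accuracy <- function(positive, negative,
                                          direction = c("low_is_positive",
                                                        "high_is_positive"),
                                          boundary = NULL) {
  direction <- match.arg(direction)
  if (!length(positive) || !length(negative))
    stop("both classes must be non-empty")
  b <- boundary %||% mean(c(positive, negative))
  side <- function(v) if (direction == "low_is_positive") {
    ifelse(v < b, 1, ifelse(v > b, 0, 0.5))
  } else {
    ifelse(v > b, 1, ifelse(v < b, 0, 0.5))
  }
  (sum(side(positive)) + sum(1 - side(negative))) /
    (length(positive) + length(negative))
}

#' Boundary sweep around the grand-mean threshold
#'
#' Exhaustive accuracy over a grid of candidate decision boundaries,
#' reporting the best boundary and its improvement over the grand-mean
#' default.
#'
#' @inheritParams univariate_threshold_accuracy
#' @param grid numeric vector of candidate boundaries.
#' @return list with `best_boundary`, `best_accuracy`,
#'   `grand_mean_accuracy` and `delta` (best minus grand mean).
#' @export
boundary_sweep <- function(positive, negative, direction, grid) {
  if (!length(grid)) stop("empty boundary grid")
  accs <- vapply(grid, function(b)
    univariate_threshold_accuracy(positive, negative, direction,
                                  boundary = b), 0)
  gm <- univariate_threshold_accuracy(positive, negative, direction)
  i <- which.max(accs)
  list(best_boundary = grid[i], best_accuracy = accs[i],
       grand_mean_accuracy = gm, delta = accs[i] - gm)
}

#' Cohen's d with pooled standard deviation
#'
#' `(mean(x) - mean(y)) / s_p` with
#' `s_p = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#'
#' @param x,y observation vectors (each >= 2 values).
#' @return the standardized mean difference.
#' @export
cohens_d <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("each group needs >= 2 observations")
  sp <- sqrt(((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2))
  if (sp == 0) stop("zero pooled standard deviation")
  (mean(x) - mean(y)) / sp
}

#' Exact two-sided binomial test against chance
#'
#' Two-sided p-value for `k` successes in `n` Bernoulli(0.5) trials by
#' the minimum-likelihood method (sum of all outcome probabilities no
#' larger than the observed outcome's), as implemented by
#' [stats::binom.test()].
#'
#' @param k_correct number of correct predictions.
#' @param n number of evaluated observations.
#' @return p-value.
#' @export
binomial_vs_chance <- function(k_correct, n) {
  stopifnot(n >= 1, k_correct >= 0, k_correct <= n)
  binom.test(round(k_correct), n, p = 0.5)$p.value
}

#' Fisher's method for combining p-values
#'
#' `chi2 = -2 * sum(log(p))` on `2k` degrees of freedom; the combined
#' p-value is the upper-tail chi-square probability. Zero p-values are
#' clipped to the smallest positive double with a warning.
#'
#' @param p_values vector of independent p-values in (0, 1].
#' @return list with `chi2`, `df`, `p`.
#' @export
fisher_combine <- function(p_values) {
  if (!length(p_values)) stop("no p-values to combine")
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  if (any(p_values == 0)) {
    warning("p-value of 0 clipped to smallest positive double")
    p_values[p_values == 0] <- .Machine$double.xmin
  }
  chi2 <- -2 * sum(log(p_values))
  df <- 2 * length(p_values)
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}

#' Benjamini-Hochberg FDR adjustment within families
#'
#' Step-up BH adjustment applied independently within each test family;
#' the univariate and multivariate tests form distinct families.
#'
#' @param p_values raw p-values.
#' @param family_labels family per test, each `"univariate"` or
#'   `"multivariate"`.
#' @return adjusted p-values, aligned with the input.
#' @export
bh_fdr <- function(p_values, family_labels) {
  if (length(p_values) != length(family_labels))
    stop("p_values and family_labels must align")
  ok <- family_labels %in% c("univariate", "multivariate")
  if (!all(ok))
    stop("unknown family label(s): ",
         paste(unique(family_labels[!ok]), collapse = ", "))
  adj <- p_values
  for (fam in unique(family_labels)) {
    sel <- family_labels == fam
    adj[sel] <- stats::p.adjust(p_values[sel], method = "BH")
  }
  adj
}

#' Combine per-participant decoding results
#'
#' Per participant an exact binomial test of the evaluation accuracy
#' against chance; the per-participant p-values combined by Fisher's
#' method; and the mean accuracy with a 95% t-interval across the
#' participant means.
#'
#' @param results list of `decode_result` objects (one per participant),
#'   or a data frame with columns `k` and `n`.
#' @return a `stats_report`: per-participant p-values, Fisher `chi2` /
#'   `df` / combined `p`, `mean_accuracy` and `ci95`.
#' @export
participant_summary <- function(results) {
  if (is.data.frame(results)) {
    k <- results$k; n <- results$n
  } else {
    k <- vapply(results, function(r) round(r$accuracy * r$n_eval), 0)
    n <- vapply(results, function(r) r$n_eval, 0)
  }
  if (length(k) < 2) stop("need >= 2 participants")
  p_each <- mapply(binomial_vs_chance, k, n)
  fc <- fisher_combine(p_each)
  accs <- k / n
  m <- length(accs)
  half <- qt(0.975, m - 1) * sd(accs) / sqrt(m)
  structure(list(p_per_participant = p_each, fisher_chi2 = fc$chi2,
                 fisher_df = fc$df, p_combined = fc$p,
                 mean_accuracy = mean(accs),
                 ci95 = mean(accs) + c(-1, 1) * half,
                 accuracies = accs),
            class = "stats_report")
}

# Jeffreys default Bayes factor for a correlation, using Jeffreys's
# approximate sampling density of r given rho,
#   L(rho) ~ (1 - rho^2)^((n-1)/2) / (1 - rho * r)^(n - 3/2),
# integrated against the stretched-beta prior of width 1 (uniform on
# (-1, 1)). Applied to rank-transformed data by the caller.
jeffreys_correlation_bf <- function(r, n) {
  stopifnot(n >= 4, abs(r) <= 1)
  # perfect rank correlation: the marginal likelihood diverges at
  # rho = r, so the evidence for an association is unbounded
  if (abs(r) >= 1 - 1e-12) return(Inf)
  lik_ratio <- function(rho)
    exp((n - 1) / 2 * log1p(-rho^2) - (n - 1.5) * log1p(-rho * r))
  0.5 * integrate(lik_ratio, -1, 1, rel.tol = 1e-8)$value
}

#' Correlate a per-participant metric with a covariate
#'
#' IQR outlier removal (either variable outside
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`), then the Spearman rank correlation
#' with its p-value, and Jeffreys's default Bayes factor (stretched-beta
#' prior, width 1) computed on the rank-transformed data, so BF10 < 1
#' quantifies evidence for the absence of a monotone association.
#'
#' @param metric per-participant metric (e.g. accuracy or mean logit
#'   difference).
#' @param covariate per-participant covariate (e.g. lifetime meditation
#'   hours, dissolution-depth index).
#' @param iqr_multiplier outlier fence width (default 1.5).
#' @return a `correlation_result`: `spearman_rho`, `p`, `bf10`,
#'   `n_after_outlier_removal`.
#' @export
covariate_correlation <- function(metric, covariate, iqr_multiplier = 1.5) {
  stopifnot(length(metric) == length(covariate))
  keep_fence <- function(v) {
    q <- quantile(v, c(0.25, 0.75), na.rm = TRUE)
    iqr <- q[2] - q[1]
    v >= q[1] - iqr_multiplier * iqr & v <= q[2] + iqr_multiplier * iqr
  }
  keep <- keep_fence(metric) & keep_fence(covariate)
  m <- metric[keep]; cv <- covariate[keep]
  if (length(m) < 5) stop("fewer than 5 participants after outlier removal")
  if (sd(m) == 0 || sd(cv) == 0)
    stop("undefined correlation: a variable is constant after filtering")
  ct <- suppressWarnings(cor.test(m, cv, method = "spearman"))
  r_rank <- stats::cor(rank(m), rank(cv))
  structure(list(spearman_rho = unname(ct$estimate), p = ct$p.value,
                 bf10 = jeffreys_correlation_bf(r_rank, length(m)),
                 n_after_outlier_removal = length(m)),
            class = "correlation_result")
}
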