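#' Chronological within-participant split
#'
#' The percent layout applied to chronologically ordered rows of a single
#' participant: the data are split in half and from each half the first
#' 80% train and the last 20% evaluate — i.e. positions 0--40% train,
#' 40--50% eval, 50--90% train, 90--100% eval. At every junction between
#' a train block and an eval block the train-side adjacent row is moved
#' to `removed` so that no eval row is chronologically adjacent to any
#' train row (leakage guard between neighbouring epochs).
#'
#' @param table a [feature_table()] of one participant, rows sorted by
#'   `epoch_idx`.
#' @return a `split_plan`: list with integer row-index vectors `train`,
#'   `eval`, `removed` and `mode = "within"`.
#' @export
within_participant_split <- function(table) {
  if (length(unique(table$participant)) != 1)
    stop("within-participant split requires a single participant")
  if (is.unsorted(table$epoch_idx))
    stop("rows must be sorted by chronological index")
  n <- nrow(table)
  if (n < 20) stop("too few rows (", n, ") for the chronological split")
  b1 <- floor(0.4 * n); b2 <- floor(0.5 * n); b3 <- floor(0.9 * n)
  eval_idx <- c(seq.int(b1 + 1, b2), seq.int(b3 + 1, n))
  train_idx <- c(seq.int(1, b1), seq.int(b2 + 1, b3))
  removed <- intersect(c(b1, b2 + 1, b3), train_idx)
  train_idx <- setdiff(train_idx, removed)
  structure(list(train = train_idx, eval = eval_idx, removed = removed,
                 mode = "within"), class = "split_plan")
}

#' Random across-participant split
#'
#' Participants (never individual rows) are assigned at random to the
#' training or evaluation set, with `round-half-up(train_fraction * P)`
#' training participants, clamped so both sides are non-empty.
#'
#' @param table a cohort [feature_table()] (>= 2 participants).
#' @param train_fraction fraction of participants in training
#'   (default 0.8).
#' @param seed integer; same seed, same assignment.
#' @return a `split_plan` with `mode = "across"` and the participant
#'   assignment in `train_participants` / `eval_participants`.
#' @export
across_participant_split <- function(table, train_fraction = 0.8, seed = 1) {
  ids <- unique(table$participant)
  P <- length(ids)
  if (P < 2) stop("across-participant split requires >= 2 participants")
  n_train <- min(P - 1L, max(1L, floor(train_fraction * P + 0.5)))
  set.seed(as.integer(seed))
  train_ids <- sample(ids, n_train)
  structure(list(train = which(table$participant %in% train_ids),
                 eval = which(!table$participant %in% train_ids),
                 removed = integer(0), mode = "across",
                 train_participants = train_ids,
                 eval_participants = setdiff(ids, train_ids)),
            class = "split_plan")
}

#' SMOTE class rebalancing
#'
#' Over-samples the minority class until class counts are equal: each
#' synthetic observation is a convex combination `x + u * (nn - x)`
#' (`u ~ U(0,1)`) of a minority observation and one of its `k_neighbors`
#' nearest minority neighbours (Euclidean distance). Already balanced
#' input is returned unchanged.
#'
#' @param x feature matrix.
#' @param y class labels (exactly two classes present).
#' @param k_neighbors neighbourhood size (default 5); reduced with a
#'   warning when the minority class is too small.
#' @param seed integer.
#' @return list with the augmented `x`, `y` and `n_synthetic`.
#' @export
smote_balance <- function(x, y, k_neighbors = 5, seed = 1) {
  y <- as.character(y)
  tab <- table(y)
  if (length(tab) < 2) stop("SMOTE requires both classes present")
  if (length(unique(tab)) == 1 && length(tab) == 2)
    return(list(x = x, y = y, n_synthetic = 0L))
  minority <- names(tab)[which.min(tab)]
  need <- max(tab) - min(tab)
  xm <- x[y == minority, , drop = FALSE]
  nm <- nrow(xm)
  if (nm < 2) stop("minority class too small for SMOTE")
  k <- k_neighbors
  if (nm <= k) {
    k <- nm - 1L
    warning("minority class has ", nm, " rows <= k_neighbors; using k = ", k)
  }
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  ord <- apply(d, 1, function(r) order(r)[seq_len(k)])
  nn <- if (k == 1) matrix(ord, ncol = 1) else t(ord)
  set.seed(as.integer(seed))
  base <- sample.int(nm, need, replace = TRUE)
  pick <- nn[cbind(base, sample.int(k, need, replace = TRUE))]
  u <- runif(need)
  synth <- xm[base, , drop = FALSE] +
    u * (xm[pick, , drop = FALSE] - xm[base, , drop = FALSE])
  list(x = rbind(x, synth), y = c(y, rep(minority, need)),
       n_synthetic = as.integer(need))
}

#' Default hyper-parameter grids
#'
#' Decade-spaced grids: LR / SVC `C` in {0.01, 0.1, 1, 10, 100}; SVC
#' `gamma` in {0.001, 0.01, 0.1, 1}; RF trees {100, 300}, depth
#' {unlimited, 5, 10}, minimum node size {2, 10}; GNB has no tunables.
#' Grids are ordered simplest-first so cross-validation ties resolve to
#' the simplest model.
#'
#' @param family one of `"lr"`, `"svc"`, `"rf"`, `"gnb"`.
#' @return data frame of candidate parameter combinations (zero-row for
#'   gnb).
#' @export
default_hyper_grid <- function(family = c("lr", "svc", "rf", "gnb")) {
  family <- match.arg(family)
  switch(family,
    lr = data.frame(C = c(0.01, 0.1, 1, 10, 100)),
    svc = expand.grid(C = c(0.01, 0.1, 1, 10, 100),
                      gamma = c(0.001, 0.01, 0.1, 1)),
    rf = expand.grid(num_trees = c(100, 300), max_depth = c(0, 5, 10),
                     min_node = c(2, 10)),
    gnb = data.frame())
}

fit_family <- function(family, x, y, params, seed = 1) {
  yf <- factor(y)
  if (family == "lr") {
    lam <- 1 / (nrow(x) * params$C)
    # at extreme regularization glmnet warns while returning the valid
    # intercept-only model; that is the expected total-shrinkage limit
    fit <- withCallingHandlers(
      glmnet::glmnet(x, yf, family = "binomial", alpha = 1,
                     lambda = lam, standardize = FALSE),
      warning = function(w) {
        if (grepl("empty model|Convergence for 1th lambda",
                  conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    list(family = family, fit = fit, lambda = lam, levels = levels(yf))
  } else if (family == "svc") {
    fit <- e1071::svm(x, yf, kernel = "radial", cost = params$C,
                      gamma = params$gamma, scale = FALSE)
    list(family = family, fit = fit, levels = levels(yf))
  } else if (family == "rf") {
    df <- data.frame(.y = yf, x, check.names = FALSE)
    fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                          num.trees = params$num_trees,
                          max.depth = params$max_depth,
                          min.node.size = params$min_node,
                          probability = TRUE, seed = seed)
    list(family = family, fit = fit, levels = levels(yf))
  } else if (family == "gnb") {
    fit <- e1071::naiveBayes(x, yf)
    list(family = family, fit = fit, levels = levels(yf))
  } else stop("unknown classifier family: ", family)
}

predict_family <- function(model, x) {
  lv <- model$levels
  if (model$family == "lr") {
    score <- as.numeric(predict(model$fit, x, type = "link"))
    list(label = lv[1 + (score > 0)], score = score)
  } else if (model$family == "svc") {
    pr <- predict(model$fit, x, decision.values = TRUE)
    dv <- as.numeric(attr(pr, "decision.values"))
    # orient the decision value so positive favours the second level
    flip <- grepl(paste0("^", lv[2], "/"), colnames(attr(pr, "decision.values")))
    list(label = as.character(pr), score = if (flip) dv else -dv)
  } else if (model$family == "rf") {
    p <- predict(model$fit, data.frame(x, check.names = FALSE))$predictions
    list(label = lv[1 + (p[, lv[2]] > 0.5)], score = p[, lv[2]] - 0.5)
  } else {
    p <- predict(model$fit, x, type = "raw")
    list(label = lv[1 + (p[, lv[2]] > p[, lv[1]])],
         score = log(pmax(p[, lv[2]], 1e-300)) - log(pmax(p[, lv[1]], 1e-300)))
  }
}

stratified_folds <- function(y, k = 5, seed = 1) {
  y <- as.character(y)
  if (min(table(y)) < k)
    stop("stratification error: a class has fewer rows than folds")
  set.seed(as.integer(seed))
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Train, tune and evaluate one classification task
#'
#' Rows are filtered to the two contrast states on each side of the
#' split; each side is SMOTE-rebalanced separately (the evaluation-side
#' rebalancing is methodologically unusual but deliberate — disable with
#' `smote_eval = FALSE`); a standard scaler is fit on the balanced
#' training rows only; hyper-parameters are chosen by grid search with
#' stratified 5-fold cross-validation maximizing accuracy (ties resolve
#' to the earliest, simplest grid entry); the winning model is refit on
#' the full training side and scored on the evaluation side.
#'
#' @param table a [feature_table()].
#' @param split a `split_plan` whose indices refer to rows of `table`.
#' @param contrast character pair of states, positive class first, e.g.
#'   `c("SBminus", "rest")`.
#' @param family classifier family (see [default_hyper_grid()]).
#' @param grid hyper-parameter grid (default [default_hyper_grid()]).
#' @param cv_folds stratified CV folds (default 5).
#' @param seed integer.
#' @param smote_eval rebalance the evaluation side too (default TRUE).
#' @param k_neighbors SMOTE neighbourhood size.
#' @return a `decode_result`: accuracy, `n_eval`, per-row predictions
#'   (label and decision score; the score is the logit for `"lr"`), best
#'   hyper-parameters, and — for `"lr"` only — per-feature coefficients.
#' @export
fit_and_evaluate <- function(table, split, contrast, family = "lr",
                             grid = default_hyper_grid(family),
                             cv_folds = 5, seed = 1, smote_eval = TRUE,
                             k_neighbors = 5) {
  stopifnot(inherits(table, "feature_table"), inherits(split, "split_plan"))
  if (length(intersect(split$train, split$eval)))
    stop("split leakage: train and eval overlap")
  feats <- feature_columns(table)
  take <- function(idx) {
    sub <- table[idx, , drop = FALSE]
    sub <- sub[sub$state %in% contrast, , drop = FALSE]
    list(x = as.matrix(sub[feats]), y = sub$state)
  }
  tr <- take(split$train)
  ev <- take(split$eval)
  if (length(unique(tr$y)) < 2 || length(unique(ev$y)) < 2)
    stop("both contrast states must be present on both split sides")
  tr <- smote_balance(tr$x, tr$y, k_neighbors, seed = seed)
  if (smote_eval) {
    ev <- smote_balance(ev$x, ev$y, k_neighbors, seed = seed + 1L)
  } else ev <- list(x = ev$x, y = ev$y, n_synthetic = 0L)
  # standard scaler from training rows only
  mu <- colMeans(tr$x)
  sdev <- apply(tr$x, 2, sd)
  sdev[sdev == 0] <- 1
  sc <- function(m) sweep(sweep(m, 2, mu), 2, sdev, `/`)
  xtr <- sc(tr$x); xev <- sc(ev$x)
  best <- list(acc = -Inf, row = NULL)
  if (nrow(grid) > 1) {
    fold <- stratified_folds(tr$y, cv_folds, seed = seed)
    for (g in seq_len(nrow(grid))) {
      params <- grid[g, , drop = FALSE]
      accs <- vapply(seq_len(cv_folds), function(f) {
        m <- fit_family(family, xtr[fold != f, , drop = FALSE],
                        tr$y[fold != f], params, seed = seed)
        mean(predict_family(m, xtr[fold == f, , drop = FALSE])$label ==
               tr$y[fold == f])
      }, 0)
      if (mean(accs) > best$acc) best <- list(acc = mean(accs), row = g)
    }
    best_params <- grid[best$row, , drop = FALSE]
  } else {
    best_params <- if (nrow(grid) == 1) grid[1, , drop = FALSE] else
      data.frame()
  }
  model <- fit_family(family, xtr, tr$y, best_params, seed = seed)
  pr <- predict_family(model, xev)
  acc <- mean(pr$label == ev$y)
  coefs <- NULL
  if (family == "lr") {
    cf <- as.numeric(coef(model$fit))[-1]
    # glmnet models P(second level); flip so positive weights favour the
    # positive (first-named) contrast state
    sgn <- if (model$levels[1] == contrast[1]) -1 else 1
    coefs <- stats::setNames(sgn * cf, feats)
    pr$score <- sgn * pr$score
  }
  structure(list(accuracy = acc, n_eval = length(ev$y),
                 predictions = data.frame(truth = ev$y, label = pr$label,
                                          score = pr$score,
                                          stringsAsFactors = FALSE),
                 best_hyperparams = best_params, coefficients = coefs,
                 family = family, contrast = contrast, mode = split$mode,
                 n_synthetic_train = tr$n_synthetic,
                 n_synthetic_eval = ev$n_synthetic),
            class = "decode_result")
}

#' Coefficient-based feature importance
#'
#' Features of an L1 logistic-regression result ranked by absolute
#' coefficient, signed values preserved; exactly-zero coefficients are
#' dropped from the ranking.
#'
#' @param result a `decode_result` with `family = "lr"`.
#' @return data frame with `feature`, `coefficient`, sorted by
#'   `|coefficient|` descending.
#' @export
feature_importance <- function(result) {
  if (is.null(result$coefficients))
    stop("unsupported family: importance is defined for 'lr' results only")
  cf <- result$coefficients[result$coefficients != 0]
  out <- data.frame(feature = names(cf), coefficient = unname(cf),
                    stringsAsFactors = FALSE)
  out[order(-abs(out$coefficient)), , drop = FALSE]
}

#' Decode one task end-to-end for a participant or cohort
#'
#' Convenience wrapper: filters the table to the contrast states,
#' constructs the split (chronological within one participant;
#' participant-level random assignment across the cohort) and calls
#' [fit_and_evaluate()].
#'
#' @inheritParams fit_and_evaluate
#' @param mode `"within"` (single participant) or `"across"`.
#' @param train_fraction across-mode train fraction.
#' @param ... passed to [fit_and_evaluate()].
#' @return a `decode_result`.
#' @export
decode_task <- function(table, contrast, mode = c("within", "across"),
                        family = "lr", seed = 1, train_fraction = 0.8, ...) {
  mode <- match.arg(mode)
  sub <- table[table$state %in% contrast, , drop = FALSE]
  sub <- sub[order(sub$participant, sub$epoch_idx), , drop = FALSE]
  class(sub) <- class(table)
  split <- if (mode == "within") within_participant_split(sub) else
    across_participant_split(sub, train_fraction, seed = seed)
  fit_and_evaluate(sub, split, contrast, family = family, seed = seed, ...)
}
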