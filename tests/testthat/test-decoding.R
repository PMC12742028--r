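test_that("chronological split reproduces the percent layout with junction removal", {
  tab <- toy_table(n = 100, p = 2)
  sp <- within_participant_split(tab)
  expect_equal(sp$eval, c(41:50, 91:100))
  expect_equal(sort(sp$removed), c(40, 51, 90))
  expect_equal(sort(c(sp$train, sp$removed, sp$eval)), 1:100)
  # eval fraction ~ 20%
  expect_equal(length(sp$eval) / 100, 0.2)
  # no adjacency between train and eval rows
  expect_false(any(outer(sp$train, sp$eval, function(a, b) abs(a - b) == 1)))
  expect_error(within_participant_split(toy_table(n = 19)), "too few")
})

test_that("across-participant split assigns whole participants", {
  tabs <- lapply(1:41, function(p)
    toy_table(n = 6, p = 2, seed = p, participant = sprintf("P%02d", p)))
  coh <- bind_feature_tables(tabs)
  sp <- across_participant_split(coh, 0.8, seed = 2)
  expect_length(sp$train_participants, 33)
  expect_length(sp$eval_participants, 8)
  expect_length(intersect(coh$participant[sp$train],
                          coh$participant[sp$eval]), 0)
  sp2 <- across_participant_split(coh, 0.8, seed = 2)
  expect_identical(sp$train_participants, sp2$train_participants)
  two <- bind_feature_tables(tabs[1:2])
  sp3 <- across_participant_split(two, 0.8, seed = 1)
  expect_length(sp3$train_participants, 1)
  expect_length(sp3$eval_participants, 1)
})

test_that("SMOTE balances classes with convex-combination synthetics", {
  set.seed(5)
  x <- matrix(rnorm(198 * 3), ncol = 3)
  y <- rep(c("a", "b"), c(100, 98))
  out <- smote_balance(x, y, seed = 7)
  expect_equal(unname(table(out$y)), c(100, 100), ignore_attr = TRUE)
  expect_equal(out$n_synthetic, 2L)
  # balanced input is untouched
  xb <- x[1:196, ]; yb <- rep(c("a", "b"), each = 98)
  expect_identical(smote_balance(xb, yb)$x, xb)
  # every synthetic row lies on a segment between two minority rows
  x2 <- matrix(rnorm(30 * 2), ncol = 2)
  y2 <- rep(c("a", "b"), c(22, 8))
  out2 <- smote_balance(x2, y2, seed = 3)
  synth <- out2$x[-seq_len(30), , drop = FALSE]
  minor <- x2[y2 == "b", ]
  on_segment <- function(s) {
    for (i in 1:7) for (j in (i + 1):8) {
      d_ij <- sqrt(sum((minor[i, ] - minor[j, ])^2))
      d_s <- sqrt(sum((minor[i, ] - s)^2)) + sqrt(sum((s - minor[j, ])^2))
      if (abs(d_s - d_ij) < 1e-9) return(TRUE)
    }
    FALSE
  }
  expect_true(all(apply(synth, 1, on_segment)))
  expect_error(smote_balance(x2, rep("a", 30)), "both classes")
  expect_warning(smote_balance(matrix(rnorm(40), ncol = 2),
                               rep(c("a", "b"), c(16, 4)), k_neighbors = 5),
                 "k = 3")
})

test_that("all four classifier families separate planted point clouds", {
  tab <- toy_table(n = 120, p = 4, delta = 10, seed = 1)
  for (fam in c("lr", "svc", "rf", "gnb")) {
    r <- decode_task(tab, c("SBminus", "rest"), mode = "within",
                     family = fam, seed = 3)
    expect_equal(r$accuracy, 1.0)
    expect_equal(r$mode, "within")
  }
})

test_that("shuffled labels decode at chance", {
  set.seed(20)
  accs <- n_evals <- numeric(20)
  for (i in 1:20) {
    tab <- toy_table(n = 120, p = 4, delta = 10, seed = 1)
    tab$state <- sample(tab$state)
    class(tab) <- c("feature_table", "data.frame")
    r <- decode_task(tab, c("SBminus", "rest"), family = "lr",
                     seed = 1000 + i)
    accs[i] <- r$accuracy; n_evals[i] <- r$n_eval
  }
  n_tot <- sum(n_evals)
  half_width <- 1.96 * sqrt(0.25 / n_tot)
  expect_lt(abs(sum(accs * n_evals) / n_tot - 0.5), half_width + 0.02)
})

test_that("extreme L1 shrinkage zeroes all coefficients and scores 0.5", {
  tab <- toy_table(n = 120, p = 4, delta = 1, seed = 2)
  r <- decode_task(tab, c("SBminus", "rest"), family = "lr", seed = 1,
                   grid = data.frame(C = 1e-8))
  expect_true(all(r$coefficients == 0))
  expect_equal(r$accuracy, 0.5)
  expect_identical(nrow(feature_importance(r)), 0L)
})

test_that("importance recovers planted single-feature effects with signs", {
  set.seed(8)
  n <- 200
  x <- matrix(rnorm(n * 6), n, 6)
  state <- rep(c("SBminus", "rest"), length.out = n)
  x[state == "SBminus", 3] <- x[state == "SBminus", 3] + 2
  x[state == "SBminus", 5] <- x[state == "SBminus", 5] - 2
  colnames(x) <- paste0("f__", 1:6)
  tab <- feature_table(cbind(data.frame(participant = "P01", state = state,
                                        epoch_idx = 1:n), as.data.frame(x)))
  r <- decode_task(tab, c("SBminus", "rest"), family = "lr", seed = 4)
  imp <- feature_importance(r)
  expect_true(imp$feature[1] %in% c("f__3", "f__5"))
  expect_gt(imp$coefficient[imp$feature == "f__3"], 0)
  expect_lt(imp$coefficient[imp$feature == "f__5"], 0)
  gnb <- decode_task(tab, c("SBminus", "rest"), family = "gnb", seed = 4)
  expect_error(feature_importance(gnb), "unsupported family")
})

test_that("split plans refuse leaking rows between sides", {
  tab <- toy_table(n = 40, p = 2)
  sp <- within_participant_split(tab)
  sp$eval <- c(sp$eval, sp$train[1])
  expect_error(fit_and_evaluate(tab, sp, c("SBminus", "rest")), "leakage")
})

test_that("multivariate LR dominates the best univariate threshold", {
  # moderate effects spread over several regions; fine-grained
  # alternation so chronological eval blocks mix both states
  p <- session_protocol(rep(c("rest", "SBminus"), 10), rep(20, 20), 300)
  eff <- effect_spec(region_count = 6,
                     complexity = rbind(rest = rep(0.25, 6),
                                        SBminus = c(rep(0.33, 4), 0.25, 0.25),
                                        SBplus = rep(0.25, 6)))
  ts <- generate_session(p, eff, seed = 41)
  tab <- lzc_feature_table(ts)
  r <- decode_task(tab, c("SBminus", "rest"), family = "lr", seed = 6)
  uni <- vapply(feature_columns(tab), function(cl)
    univariate_threshold_accuracy(tab[tab$state == "SBminus", cl],
                                  tab[tab$state == "rest", cl],
                                  "high_is_positive"), 0)
  expect_gte(r$accuracy, max(uni) - 0.02)
})
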