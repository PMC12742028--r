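#!/usr/bin/env Rscript
# Step 3 - decode the mental state from the feature tables.
#
# For each feature set (LZc, corrected 27 Hz band power, aperiodic
# exponent) and both contrasts, within-participant decoding uses the
# chronological 40/10/40/10 percent split with junction epochs removed,
# SMOTE rebalancing per side, train-fitted standard scaling and
# grid-searched L1 logistic regression; across-participant decoding
# assigns whole participants to the sides at random. Also runs a
# grand-mean threshold benchmark per region for the univariate family.

library(megstates)

seed <- 20260919
lzc <- load_feature_table("results/features_lzc.tsv")
spec <- load_feature_table("results/features_spectral.tsv")

sets <- list(lzc = lzc,
             beta27 = feature_table(spec[c("participant", "state", "epoch_idx",
                                           grep("^beta27__", names(spec),
                                                value = TRUE))]),
             aperiodic = feature_table(spec[c("participant", "state",
                                              "epoch_idx",
                                              grep("^aperiodic__", names(spec),
                                                   value = TRUE))]))
contrasts <- list(sbm_vs_rest = c("SBminus", "rest"),
                  sbm_vs_sbp = c("SBminus", "SBplus"))

rows <- list(); uni_rows <- list(); imp <- NULL
for (fs in names(sets)) for (cn in names(contrasts)) {
  tab <- sets[[fs]]
  states <- contrasts[[cn]]
  ids <- unique(tab$participant)
  within <- lapply(ids, function(pid) {
    sub <- tab[tab$participant == pid, , drop = FALSE]
    class(sub) <- class(tab)
    decode_task(sub, states, mode = "within", family = "lr", seed = seed)
  })
  ws <- participant_summary(within)
  across <- decode_task(tab, states, mode = "across", family = "lr",
                        seed = seed)
  rows[[paste(fs, cn, "within")]] <- data.frame(
    feature = fs, contrast = cn, mode = "within",
    accuracy = ws$mean_accuracy, p = ws$p_combined)
  rows[[paste(fs, cn, "across")]] <- data.frame(
    feature = fs, contrast = cn, mode = "across",
    accuracy = across$accuracy,
    p = binomial_vs_chance(round(across$accuracy * across$n_eval),
                           across$n_eval))
  if (fs == "lzc" && cn == "sbm_vs_rest")
    imp <- feature_importance(across)
  # univariate benchmark: grand-mean threshold per region, pooled epochs
  dir <- if (fs == "lzc") "high_is_positive" else "low_is_positive"
  uni <- vapply(feature_columns(tab), function(cl)
    univariate_threshold_accuracy(tab[tab$state == states[1], cl],
                                  tab[tab$state == states[2], cl], dir), 0)
  k_best <- round(max(uni) * sum(tab$state %in% states))
  uni_rows[[paste(fs, cn)]] <- data.frame(
    feature = fs, contrast = cn, mode = "pooled",
    accuracy = max(uni),
    p = binomial_vs_chance(k_best, sum(tab$state %in% states)))
}

multi <- do.call(rbind, rows)
uni <- do.call(rbind, uni_rows)
multi$family <- "multivariate"; uni$family <- "univariate"
res <- rbind(multi, uni)
res$p_fdr <- bh_fdr(res$p, res$family)
write.table(res, "results/decode_tasks.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(imp, "results/importance_lzc_sbm_vs_rest.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(res[c("feature", "contrast", "mode", "accuracy", "p_fdr")],
      digits = 3)
cat("Top regions by |coefficient| (LZc, SBminus vs rest, across):\n")
print(head(imp, 5))
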