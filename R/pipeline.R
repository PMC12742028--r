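#' Run configuration
#'
#' Collects everything one end-to-end run needs. `features` selects
#' feature sets by name: `"lzc"`, `"aperiodic"`, or `"band:<name>"` with
#' a band from [default_bands()]. `contrasts` are `"sbm_vs_rest"` and/or
#' `"sbm_vs_sbp"`. The master seed is expanded deterministically into
#' per-stage child seeds (cohort generation, splitting, decoding), so a
#' stage can be re-run in isolation.
#'
#' @param n_participants cohort size.
#' @param effects an [effect_spec()] or a preset name for
#'   [effect_preset()].
#' @param between_participant_sd cohort spread (see [generate_cohort()]).
#' @param protocol a [session_protocol()].
#' @param features character vector of feature-set selectors.
#' @param contrasts character vector of contrast names.
#' @param modes `"within"` and/or `"across"`.
#' @param classifiers subset of `c("lr", "svc", "rf", "gnb")`.
#' @param seed master seed.
#' @param out_dir optional output directory for the results bundle.
#' @param smote_eval rebalance evaluation sets (default TRUE).
#' @return a `run_config` list.
#' @export
run_config <- function(n_participants = 10, effects = "small_to_medium",
                       between_participant_sd = 0.3,
                       protocol = default_protocol(),
                       features = "lzc",
                       contrasts = c("sbm_vs_rest", "sbm_vs_sbp"),
                       modes = c("within", "across"),
                       classifiers = "lr", seed = 1, out_dir = NULL,
                       smote_eval = TRUE) {
  if (is.character(effects)) effects <- effect_preset(effects)
  stopifnot(inherits(effects, "effect_spec"),
            all(modes %in% c("within", "across")),
            all(classifiers %in% c("lr", "svc", "rf", "gnb")),
            all(contrasts %in% c("sbm_vs_rest", "sbm_vs_sbp")))
  band_names <- names(default_bands())
  for (f in features) {
    ok <- f %in% c("lzc", "aperiodic") ||
      (startsWith(f, "band:") && sub("band:", "", f) %in% band_names)
    if (!ok) stop("unknown feature selector: ", f)
  }
  if (is.null(seed)) stop("a seed is required (no silent nondeterminism)")
  structure(list(n_participants = n_participants, effects = effects,
                 between_participant_sd = between_participant_sd,
                 protocol = protocol, features = features,
                 contrasts = contrasts, modes = modes,
                 classifiers = classifiers, seed = as.integer(seed),
                 out_dir = out_dir, smote_eval = smote_eval),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognised keys: `n_participants`, `preset` (effect preset name),
#' `between_participant_sd`, `features`, `contrasts`, `modes`,
#' `classifiers`, `seed`, `out_dir`, `region_count`, and optional
#' `protocol` (list with `states`, `durations_s`, `sampling_rate`).
#'
#' @param path YAML file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  protocol <- if (!is.null(y$protocol)) {
    session_protocol(unlist(y$protocol$states),
                     unlist(y$protocol$durations_s),
                     y$protocol$sampling_rate %||% 300)
  } else default_protocol()
  effects <- effect_preset(y$preset %||% "small_to_medium",
                           region_count = y$region_count %||% 62)
  run_config(n_participants = y$n_participants %||% 10,
             effects = effects,
             between_participant_sd = y$between_participant_sd %||% 0.3,
             protocol = protocol,
             features = unlist(y$features) %||% "lzc",
             contrasts = unlist(y$contrasts) %||% c("sbm_vs_rest", "sbm_vs_sbp"),
             modes = unlist(y$modes) %||% c("within", "across"),
             classifiers = unlist(y$classifiers) %||% "lr",
             seed = y$seed, out_dir = y$out_dir)
}

contrast_states <- function(name)
  switch(name, sbm_vs_rest = c("SBminus", "rest"),
         sbm_vs_sbp = c("SBminus", "SBplus"),
         stop("unknown contrast: ", name))

feature_prefix <- function(selector)
  if (startsWith(selector, "band:")) sub("band:", "", selector) else selector

select_feature_set <- function(table, selector) {
  pre <- paste0(feature_prefix(selector), "__")
  cols <- grep(paste0("^", pre), names(table), value = TRUE)
  if (!length(cols)) stop("no columns for feature selector ", selector)
  feature_table(table[c("participant", "state", "epoch_idx", cols)])
}

needs_spectral <- function(features)
  any(features == "aperiodic" | startsWith(features, "band:"))

#' Compute per-participant feature tables for a synthetic cohort
#'
#' Streams participants one at a time (generate, featurize, discard the
#' raw signal) to bound memory, using the same per-participant parameter
#' draws as [generate_cohort()].
#'
#' @inheritParams generate_cohort
#' @param features feature selectors (see [run_config()]).
#' @param bands band definitions for the spectral table.
#' @return a list with up to two cohort [feature_table()]s: `lzc` (4 s
#'   epochs) and `spectral` (1 s epochs) — the two granularities cannot
#'   share rows.
#' @export
cohort_feature_tables <- function(n_participants, effects,
                                  between_participant_sd = 0.3, seed = 1,
                                  protocol = default_protocol(),
                                  features = "lzc",
                                  bands = default_bands()) {
  pars <- cohort_params(n_participants, effects, between_participant_sd, seed)
  lz <- list(); sp <- list()
  for (p in seq_len(n_participants)) {
    ts <- generate_session(protocol, pars$effects[[p]],
                           seed = pars$seeds[p], participant_id = pars$ids[p])
    if ("lzc" %in% features) lz[[p]] <- lzc_feature_table(ts)
    if (needs_spectral(features))
      sp[[p]] <- spectral_feature_table(ts, bands = bands)
  }
  out <- list()
  if (length(lz)) out$lzc <- bind_feature_tables(lz)
  if (length(sp)) out$spectral <- bind_feature_tables(sp)
  out
}

#' Run the full pipeline from one configuration
#'
#' simulate -> features -> decode -> statistics. For every combination of
#' feature set, contrast, mode and classifier family the decoder is
#' trained and evaluated; within-participant tasks are summarized across
#' participants (Fisher-combined binomial p-values, mean accuracy with
#' 95% CI), across-participant tasks get a single binomial test; all
#' p-values are then BH-FDR adjusted as one multivariate family. For L1
#' logistic regression tasks, coefficient-based importance tables are
#' attached. With `out_dir` set, the bundle is written as JSON/TSV plus
#' a manifest with content hashes.
#'
#' @param config a [run_config()].
#' @return a `results_bundle` list: `tasks` (one row per task with
#'   accuracy, p, adjusted p), `importance` (named list of data frames),
#'   `per_participant` accuracies, and the `config` echo.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  child <- sample.int(.Machine$integer.max - 1L, 3)  # cohort, split, decode
  message("stage simulate+features: ", config$n_participants,
          " participants")
  cohort_tabs <- cohort_feature_tables(
    config$n_participants, config$effects, config$between_participant_sd,
    seed = child[1], protocol = config$protocol, features = config$features)
  tasks <- list()
  importance <- list()
  per_participant <- list()
  ti <- 0L
  for (feat in config$features) {
    src <- if (feat == "lzc") cohort_tabs$lzc else cohort_tabs$spectral
    ft <- select_feature_set(src, feat)
    ft <- ft[stats::complete.cases(ft), , drop = FALSE]
    class(ft) <- c("feature_table", "data.frame")
    for (ctr in config$contrasts) for (mode in config$modes)
      for (fam in config$classifiers) {
        ti <- ti + 1L
        message("stage decode: ", feat, " / ", ctr, " / ", mode, " / ", fam)
        states <- contrast_states(ctr)
        task_seed <- (child[3] + ti * 1009L) %% (.Machine$integer.max - 1L)
        if (mode == "within") {
          ids <- unique(ft$participant)
          res <- lapply(ids, function(pid) {
            sub <- ft[ft$participant == pid, , drop = FALSE]
            class(sub) <- class(ft)
            decode_task(sub, states, mode = "within", family = fam,
                        seed = task_seed, smote_eval = config$smote_eval)
          })
          summ <- participant_summary(res)
          acc <- summ$mean_accuracy
          pval <- summ$p_combined
          per_participant[[paste(feat, ctr, fam, sep = "|")]] <-
            stats::setNames(summ$accuracies, ids)
          if (fam == "lr") {
            cf <- rowMeans(vapply(res, function(r) r$coefficients,
                                  res[[1]]$coefficients))
            fake <- list(coefficients = cf)
            importance[[paste(feat, ctr, "within", sep = "|")]] <-
              feature_importance(fake)
          }
        } else {
          r <- decode_task(ft, states, mode = "across", family = fam,
                           seed = task_seed, smote_eval = config$smote_eval)
          acc <- r$accuracy
          pval <- binomial_vs_chance(round(r$accuracy * r$n_eval), r$n_eval)
          if (fam == "lr")
            importance[[paste(feat, ctr, "across", sep = "|")]] <-
              feature_importance(r)
        }
        tasks[[ti]] <- data.frame(feature = feat, contrast = ctr,
                                  mode = mode, classifier = fam,
                                  accuracy = acc, p = pval,
                                  stringsAsFactors = FALSE)
      }
  }
  tasks <- do.call(rbind, tasks)
  tasks$p_fdr <- bh_fdr(tasks$p, rep("multivariate", nrow(tasks)))
  tasks$significant <- tasks$p_fdr < 0.05
  bundle <- structure(list(tasks = tasks, importance = importance,
                           per_participant = per_participant,
                           config = config),
                      class = "results_bundle")
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- file.path(dir, "tasks.tsv")
  write.table(bundle$tasks, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "results.json")
  jsonlite::write_json(
    list(tasks = bundle$tasks,
         per_participant = bundle$per_participant),
    p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  for (nm in names(bundle$importance)) {
    p <- file.path(dir, paste0("importance_", gsub("[|:]", "_", nm), ".tsv"))
    write.table(bundle$importance[[nm]], p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, p)
  }
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Render a human-readable summary of a results bundle
#'
#' Markdown: one row per task (feature x contrast x mode x classifier)
#' with accuracy, combined/binomial p and FDR flag, plus a top-10
#' importance table per L1 logistic-regression task.
#'
#' @param bundle a `results_bundle` from [run_pipeline()].
#' @param top_n importance rows per task (default 10).
#' @return character vector of markdown lines (invisibly printed with
#'   `cat`).
#' @export
render_report <- function(bundle, top_n = 10) {
  t <- bundle$tasks
  lines <- c("# Decoding results", "",
             "| feature | contrast | mode | classifier | accuracy | p | FDR p | sig |",
             "|---|---|---|---|---|---|---|---|",
             sprintf("| %s | %s | %s | %s | %.3f | %.3g | %.3g | %s |",
                     t$feature, t$contrast, t$mode, t$classifier,
                     t$accuracy, t$p, t$p_fdr,
                     ifelse(t$significant, "*", "")))
  for (nm in names(bundle$importance)) {
    imp <- head(bundle$importance[[nm]], top_n)
    lines <- c(lines, "", paste0("## Importance: ", nm), "",
               "| feature | coefficient |", "|---|---|",
               sprintf("| %s | %.4f |", imp$feature, imp$coefficient))
  }
  invisible(lines)
}
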