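#' Feature tables
#'
#' A `feature_table` is a data frame with metadata columns
#' `participant`, `state`, `epoch_idx` (chronological within participant)
#' followed by one numeric column per feature, named
#' `<feature>__<region>` (e.g. `lzc__Precuneus_L`, `beta__Insula_R`,
#' `aperiodic__Thalamus_L`). One row per epoch.
#'
#' @param df data frame to validate.
#' @return the validated `feature_table`.
#' @export
feature_table <- function(df) {
  meta <- c("participant", "state", "epoch_idx")
  if (!all(meta %in% names(df)))
    stop("schema error: missing metadata column(s): ",
         paste(setdiff(meta, names(df)), collapse = ", "))
  bad <- setdiff(unique(df$state), STATES)
  if (length(bad))
    stop("schema error: unknown state label(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(df[c("participant", "epoch_idx")]))
    stop("schema error: duplicate (participant, epoch_idx) keys")
  feat <- setdiff(names(df), meta)
  if (!all(vapply(df[feat], is.numeric, logical(1))))
    stop("schema error: non-numeric feature column(s)")
  df <- df[c(meta, feat)]
  class(df) <- c("feature_table", "data.frame")
  df
}

#' @rdname feature_table
#' @param table a `feature_table`.
#' @return `feature_columns`: names of the feature (non-metadata) columns.
#' @export
feature_columns <- function(table) {
  setdiff(names(table), c("participant", "state", "epoch_idx"))
}

#' Read / write feature tables as TSV
#'
#' Values are written with 15 significant digits, so a save/load round
#' trip is lossless well beyond 12 significant digits; row order is
#' preserved.
#'
#' @param table a [feature_table()].
#' @param path file path (TSV).
#' @export
save_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  out <- table
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) formatC(x, digits = 15,
                                                   format = "g"))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname save_feature_table
#' @return `load_feature_table` returns the [feature_table()].
#' @export
load_feature_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$participant <- as.character(df$participant)
  feature_table(df)
}

#' Combine per-participant feature tables into a cohort table
#' @param tables list of [feature_table()].
#' @return a single [feature_table()].
#' @export
bind_feature_tables <- function(tables) {
  feature_table(do.call(rbind, lapply(tables, as.data.frame)))
}
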