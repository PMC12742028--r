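#' Atlas merge map
#'
#' Reads a two-column TSV (`raw_label`, `merged_label`) describing how
#' raw atlas labels collapse into the merged feature namespace; rows with
#' `merged_label == "EXCLUDE"` contribute no features. The packaged
#' default reproduces the cardinality of the modified AAL parcellation
#' used for MEG source features: all Cerebellum and Vermis labels
#' excluded and small cortical/subcortical regions merged so exactly 62
#' regions remain. The shipped merge scheme is a synthetic stand-in with
#' the correct cardinality (the original merged-region listing lives in a
#' supplementary table that is not redistributed here); downstream code
#' depends only on label cardinality and consistency.
#'
#' @param path TSV path; default the packaged
#'   `aal62_merge_synthetic.tsv`.
#' @return An `atlas_map`: data frame with `raw_label`, `merged_label`.
#' @export
load_atlas_map <- function(path = system.file("extdata",
                                              "aal62_merge_synthetic.tsv",
                                              package = "megstates")) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("raw_label", "merged_label") %in% names(tab)))
    stop("atlas map must have columns raw_label, merged_label")
  if (anyDuplicated(tab$raw_label))
    stop("atlas map: duplicated raw labels")
  class(tab) <- c("atlas_map", "data.frame")
  tab
}

#' Merged region labels of an atlas map
#' @param atlas an `atlas_map` (default: packaged map).
#' @return character vector of merged region labels (EXCLUDE dropped),
#'   in first-appearance order.
#' @export
atlas_region_labels <- function(atlas = load_atlas_map()) {
  unique(atlas$merged_label[atlas$merged_label != "EXCLUDE"])
}

#' Aggregate voxel values to atlas regions
#'
#' Each voxel is assigned to its raw atlas label; region values are the
#' unweighted mean over all voxels whose merged label matches. Excluded
#' labels are absent from the output. The result is invariant to voxel
#' enumeration order, and total signal is conserved: the sum over regions
#' of mean x voxel-count equals the sum of all included voxel values.
#'
#' @param voxel_values named numeric vector (names = voxel ids) or
#'   unnamed vector aligned with `voxel_labels`.
#' @param voxel_labels raw atlas label per voxel.
#' @param atlas an `atlas_map`.
#' @return named numeric vector: merged region -> mean value.
#' @export
parcellate <- function(voxel_values, voxel_labels, atlas = load_atlas_map()) {
  if (length(voxel_values) != length(voxel_labels))
    stop("voxel_values and voxel_labels must align")
  unknown <- setdiff(unique(voxel_labels), atlas$raw_label)
  if (length(unknown))
    stop("voxel(s) with unknown atlas label: ",
         paste(unknown, collapse = ", "))
  merged <- atlas$merged_label[match(voxel_labels, atlas$raw_label)]
  keep <- merged != "EXCLUDE"
  if (!any(keep)) return(stats::setNames(numeric(0), character(0)))
  m <- tapply(voxel_values[keep], merged[keep], mean)
  out <- stats::setNames(as.numeric(m), names(m))
  # stable order: first appearance in the atlas map
  out[intersect(atlas_region_labels(atlas), names(out))]
}
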