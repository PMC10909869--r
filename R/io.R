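# File interchange: NIfTI-1 volumes via RNifti, tables as CSV.

#' Write a volume (or relevance map) as NIfTI-1
#'
#' @param volume 3D or 4D numeric array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_volume_nifti <- function(volume, path) {
  RNifti::writeNifti(RNifti::asNifti(unclass(volume)), path)
  invisible(path)
}

#' Read a NIfTI-1 volume as a plain array
#'
#' @param path input path.
#' @return numeric array.
#' @export
read_volume_nifti <- function(path) {
  v <- RNifti::readNifti(path)
  array(as.vector(v), dim = dim(v))
}

#' Write an atlas as NIfTI plus an id,name CSV
#'
#' @param atlas a [make_toy_atlas()] object.
#' @param nifti_path,names_path output paths.
#' @return invisibly, the two paths.
#' @export
write_atlas <- function(atlas, nifti_path, names_path) {
  write_volume_nifti(atlas$labels, nifti_path)
  utils::write.csv(data.frame(id = as.integer(names(atlas$names)),
                              name = unname(atlas$names)),
                   names_path, row.names = FALSE)
  invisible(c(nifti_path, names_path))
}

#' Write cohort tables as CSV
#'
#' Events: `subject_id, day, label`. Scans: `subject_id, modality, day,
#' path, label` (the `path` column holds the scan id when volumes are kept
#' in memory).
#'
#' @param events events data.frame.
#' @param scans list of scan records.
#' @param events_path,scans_path output paths.
#' @return invisibly, the two paths.
#' @export
write_cohort_csv <- function(events, scans, events_path, scans_path) {
  utils::write.csv(events[c("subject_id", "day", "label")], events_path,
                   row.names = FALSE)
  tab <- scan_table(scans)
  utils::write.csv(data.frame(subject_id = tab$subject_id,
                              modality = tab$modality, day = tab$day,
                              path = tab$scan_id, label = tab$label),
                   scans_path, row.names = FALSE)
  invisible(c(events_path, scans_path))
}

#' Write a region attribution table as CSV
#'
#' Columns: `region`, `mean_relevance`, `selected`, and (when available)
#' `selection_frequency`.
#'
#' @param attribution a [region_attribution()] or [group_attribution()]
#'   result.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_attribution_csv <- function(attribution, path) {
  if (!is.null(attribution$group)) {
    ra <- attribution$group
    df <- data.frame(region = names(ra$means), mean_relevance = ra$means,
                     selected = names(ra$means) %in% ra$selected,
                     selection_frequency =
                       attribution$selection_frequency[names(ra$means)])
  } else {
    df <- data.frame(region = names(attribution$means),
                     mean_relevance = attribution$means,
                     selected = names(attribution$means) %in%
                       attribution$selected)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
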