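#' Construct a 4-D fMRI run
#'
#' A run is one subject's 4-D acquisition stored time-first, `dim(data) =
#' c(t, x, y, z)`, together with its repetition time and (optionally) a brain
#' mask. The affine is carried through I/O untouched; nothing in the package
#' interprets it.
#'
#' @param data 4-D numeric array indexed `(t, x, y, z)`.
#' @param tr_s Repetition time in seconds (> 0).
#' @param subject_id Subject identifier string.
#' @param affine 4x4 voxel-to-world matrix, carried but not interpreted.
#' @param brain_mask Optional 3-D logical array matching the spatial shape.
#' @return An object of class `fmri_run`.
#' @export
new_run <- function(data, tr_s, subject_id = "sub-01", affine = diag(4),
                    brain_mask = NULL) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop_fc("run data must be a 4-D array (t, x, y, z); got ",
            length(dim(data)), " dimension(s)")
  if (dim(data)[1] < 1L) stop_fc("run must contain at least one frame")
  if (!is.numeric(tr_s) || length(tr_s) != 1L || !is.finite(tr_s) || tr_s <= 0)
    stop_fc("tr_s must be a single positive number of seconds")
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    stop_fc("affine must be a 4x4 matrix")
  if (!is.null(brain_mask)) {
    if (!is.array(brain_mask) || length(dim(brain_mask)) != 3L)
      stop_fc("brain_mask must be a 3-D array")
    if (!all(dim(brain_mask) == dim(data)[2:4]))
      stop_fc("brain_mask shape ", paste(dim(brain_mask), collapse = "x"),
              " does not match run spatial shape ",
              paste(dim(data)[2:4], collapse = "x"))
    storage.mode(brain_mask) <- "logical"
  }
  structure(
    list(data = data, tr_s = as.numeric(tr_s),
         subject_id = as.character(subject_id),
         affine = affine, brain_mask = brain_mask),
    class = "fmri_run"
  )
}

#' Construct a clip (temporal excerpt of a run)
#'
#' @param data 4-D numeric array `(t, x, y, z)`.
#' @param tr_s Repetition time in seconds.
#' @param subject_id Subject identifier.
#' @param label Optional condition label.
#' @param source_span Half-open, 0-based frame interval `c(lo, hi)` in the
#'   parent run; its length must equal the clip's frame count.
#' @return An object of class `fmri_clip`.
#' @export
new_clip <- function(data, tr_s, subject_id = "sub-01", label = NULL,
                     source_span = c(0L, dim(data)[1])) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop_fc("clip data must be a 4-D array (t, x, y, z)")
  if (dim(data)[1] < 1L) stop_fc("clip must contain at least one frame")
  if (!is.numeric(tr_s) || length(tr_s) != 1L || tr_s <= 0)
    stop_fc("tr_s must be a single positive number of seconds")
  source_span <- as.integer(source_span)
  if (length(source_span) != 2L || diff(source_span) != dim(data)[1])
    stop_fc("source_span length must equal the clip's frame count")
  structure(
    list(data = data, tr_s = as.numeric(tr_s),
         subject_id = as.character(subject_id),
         label = if (is.null(label)) NULL else as.character(label),
         source_span = source_span),
    class = "fmri_clip"
  )
}

#' @export
print.fmri_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<fmri_run> %s: %d frames x (%d, %d, %d) voxels, TR %.3g s%s\n",
              x$subject_id, d[1], d[2], d[3], d[4], x$tr_s,
              if (is.null(x$brain_mask)) "" else ", with brain mask"))
  invisible(x)
}

#' @export
print.fmri_clip <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<fmri_clip> %s%s: %d frames x (%d, %d, %d) voxels, frames [%d, %d)\n",
    x$subject_id,
    if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
    d[1], d[2], d[3], d[4], x$source_span[1], x$source_span[2]))
  invisible(x)
}

#' Number of frames of a run or clip
#' @param x An `fmri_run` or `fmri_clip`.
#' @return Integer frame count.
#' @export
n_frames <- function(x) dim(x$data)[1]

#' Spatial shape of a run or clip
#' @param x An `fmri_run` or `fmri_clip`.
#' @return Integer vector of the three spatial extents.
#' @export
spatial_shape <- function(x) dim(x$data)[2:4]
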