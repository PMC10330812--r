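#' Load a 4-D fMRI run from a NIfTI file
#'
#' Reads a `.nii`/`.nii.gz` volume and returns it time-first, i.e. with
#' `dim(data) = c(t, x, y, z)` regardless of the on-disk `(x, y, z, t)`
#' order. The repetition time is taken from the header (`pixdim[5]`) unless
#' overridden.
#'
#' @param path Path to a 4-D NIfTI file.
#' @param tr_s Optional TR override in seconds. Required when the header
#'   carries no usable TR.
#' @param subject_id Subject identifier attached to the run.
#' @return An [new_run()] object.
#' @export
load_run <- function(path, tr_s = NULL, subject_id = "sub-01") {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop_fc("expected a 4-D NIfTI volume, got ", length(d),
            " dimension(s) in ", path)
  hdr_tr <- RNifti::pixdim(img)[4]
  if (is.null(tr_s)) {
    if (is.na(hdr_tr) || hdr_tr <= 0)
      stop_fc("NIfTI header of ", path, " carries no usable TR ",
              "(pixdim[5] = ", hdr_tr, "); pass tr_s explicitly")
    tr_s <- hdr_tr
  }
  affine <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  arr <- array(as.numeric(img), dim = d)
  new_run(aperm(arr, c(4, 1, 2, 3)), tr_s = tr_s, subject_id = subject_id,
          affine = affine)
}

#' Save a run to a NIfTI file
#'
#' Writes the run in conventional `(x, y, z, t)` order with the TR stored in
#' `pixdim[5]` and the affine in the sform/qform.
#'
#' @param run An [new_run()] object.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
save_run <- function(run, path) {
  stopifnot(inherits(run, "fmri_run"))
  arr <- aperm(run$data, c(2, 3, 4, 1))
  px <- sqrt(colSums(run$affine[1:3, 1:3]^2))
  px[px == 0] <- 1
  attr(arr, "pixdim") <- c(px, run$tr_s)
  img <- RNifti::asNifti(arr, datatype = "double")
  RNifti::sform(img) <- structure(run$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Load a 3-D mask volume
#'
#' @param path Path to a 3-D NIfTI file.
#' @param labels If `TRUE`, return the integer label volume (e.g. a Yeo-7
#'   network parcellation); otherwise return a logical mask (`!= 0`).
#' @return A 3-D logical or integer array.
#' @export
load_mask <- function(path, labels = FALSE) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- array(unclass(img), dim = d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L)
    stop_fc("expected a 3-D mask volume, got ", length(d), " dimension(s)")
  arr <- array(unclass(img), dim = d)
  if (labels) array(as.integer(round(arr)), dim = d) else arr != 0
}

#' Extract one network's binary mask from an integer-labelled parcellation
#'
#' @param labels 3-D integer array of network labels (0 = background).
#' @param id Network label to select.
#' @return 3-D logical array.
#' @export
network_mask <- function(labels, id) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop_fc("labels must be a 3-D array")
  labels == id
}

#' Read a block/event timing table
#'
#' Tab-separated with header `onset`, `duration`, `condition` (onsets and
#' durations in seconds, BIDS-events dialect). Rows are returned sorted by
#' onset.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with columns `onset`, `duration`, `condition`.
#' @export
read_events <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validate_events(df)
}

#' @rdname read_events
#' @param events Event `data.frame` to write.
#' @export
write_events <- function(events, path) {
  events <- validate_events(events)
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_events <- function(df) {
  need <- c("onset", "duration", "condition")
  if (!all(need %in% names(df)))
    stop_fc("event table must have columns ", paste(need, collapse = ", "))
  df <- df[order(df$onset), need, drop = FALSE]
  if (any(!is.finite(df$onset)) || any(df$onset < 0))
    stop_fc("event onsets must be finite and >= 0 seconds")
  if (any(!is.finite(df$duration)) || any(df$duration <= 0))
    stop_fc("event durations must be positive seconds")
  df$condition <- as.character(df$condition)
  rownames(df) <- NULL
  df
}

#' Convert a duration in seconds to a frame count
#'
#' `round(duration_s / tr_s)` to the nearest integer, halves away from zero;
#' with this convention every published (frames, seconds) pair for TR 0.72 s
#' and TR 2 s block paradigms is reproduced exactly.
#'
#' @param duration_s Duration in seconds (>= 0).
#' @param tr_s Repetition time in seconds (> 0).
#' @return Integer frame count (vectorised over `duration_s`).
#' @export
frames_for_duration <- function(duration_s, tr_s) {
  if (!is.numeric(tr_s) || length(tr_s) != 1L || tr_s <= 0)
    stop_fc("tr_s must be a single positive number")
  if (any(!is.finite(duration_s)) || any(duration_s < 0))
    stop_fc("duration_s must be finite and >= 0")
  as.integer(round_half_up(duration_s / tr_s))
}

#' Bounding box of the nonzero voxels of a mask
#'
#' Returns the smallest axis-aligned box containing every `TRUE` voxel.
#' Intervals are 0-based and half-open: `lo[i] <= v < hi[i]` on each axis.
#'
#' @param mask 3-D logical (or numeric, nonzero = in) array with at least one
#'   `TRUE` voxel.
#' @return An object of class `bbox` with fields `lo`, `hi` (length-3
#'   integer vectors).
#' @export
compute_bbox <- function(mask) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop_fc("mask must be a 3-D array")
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop_fc("mask is empty: no nonzero voxel")
  lo <- apply(idx, 2, min) - 1L
  hi <- apply(idx, 2, max)
  new_bbox(lo, hi)
}

#' Construct a bounding box
#'
#' @param lo,hi Length-3 integer vectors; 0-based half-open interval
#'   `[lo, hi)` per spatial axis, `lo < hi`.
#' @return An object of class `bbox`.
#' @export
new_bbox <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (length(lo) != 3L || length(hi) != 3L)
    stop_fc("bbox lo/hi must have length 3")
  if (any(lo < 0) || any(lo >= hi))
    stop_fc("bbox requires 0 <= lo < hi on every axis")
  structure(list(lo = lo, hi = hi), class = "bbox")
}

#' @export
print.bbox <- function(x, ...) {
  cat(sprintf("<bbox> [%d,%d) x [%d,%d) x [%d,%d), size %s\n",
              x$lo[1], x$hi[1], x$lo[2], x$hi[2], x$lo[3], x$hi[3],
              paste(bbox_size(x), collapse = "x")))
  invisible(x)
}

#' Size of a bounding box along each axis
#' @param bbox A `bbox`.
#' @return Length-3 integer vector.
#' @export
bbox_size <- function(bbox) bbox$hi - bbox$lo

#' Crop a volume, run or clip to a bounding box
#'
#' Spatial axes are restricted to the box; a temporal axis, if present, is
#' untouched. Values are preserved.
#'
#' @param x A 3-D array, 4-D `(t, x, y, z)` array, `fmri_run` or `fmri_clip`.
#' @param bbox A [new_bbox()] lying within the spatial extent of `x`.
#' @return The same kind of object, spatially restricted.
#' @export
crop <- function(x, bbox) {
  stopifnot(inherits(bbox, "bbox"))
  if (inherits(x, "fmri_run")) {
    out <- x
    out$data <- crop(x$data, bbox)
    if (!is.null(x$brain_mask)) out$brain_mask <- crop(x$brain_mask, bbox)
    return(out)
  }
  if (inherits(x, "fmri_clip")) {
    out <- x
    out$data <- crop(x$data, bbox)
    return(out)
  }
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop_fc("crop expects a 3-D or 4-D array, fmri_run or fmri_clip")
  sp <- if (length(d) == 4L) d[2:4] else d
  if (any(bbox$hi > sp))
    stop_fc("bbox [", paste(bbox$hi, collapse = ","),
            ") exceeds spatial extent (", paste(sp, collapse = ","), ")")
  ix <- lapply(1:3, function(a) (bbox$lo[a] + 1L):bbox$hi[a])
  if (length(d) == 4L) {
    x[, ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  } else {
    x[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  }
}

#' Restrict a run to one brain network's voxels
#'
#' Voxels outside the mask are zeroed and the result is cropped to the
#' mask's bounding box -- the ROI-input convention for network-wise decoding
#' (e.g. Yeo-7 parcels), which trims the blank margins around the network to
#' save computation.
#'
#' @param run An `fmri_run`.
#' @param mask 3-D logical array with the run's spatial shape.
#' @return An `fmri_run` restricted to the mask's bounding box, with the
#'   cropped mask attached as `brain_mask`.
#' @export
apply_network_mask <- function(run, mask) {
  stopifnot(inherits(run, "fmri_run"))
  if (!is.array(mask) || length(dim(mask)) != 3L ||
      !all(dim(mask) == spatial_shape(run)))
    stop_fc("mask shape must equal run spatial shape ",
            paste(spatial_shape(run), collapse = "x"))
  mask <- mask != 0
  bb <- compute_bbox(mask)
  keep <- aperm(array(mask, dim = c(dim(mask), n_frames(run))), c(4, 1, 2, 3))
  out <- run
  out$data <- run$data * keep
  out$brain_mask <- mask
  crop(out, bb)
}

#' Extract a block-covering clip from a run
#'
#' The clip covers the frames of one task block plus `pad_before` /
#' `pad_after` extra frames on either side: frames
#' `[round(onset_s/tr_s) - pad_before,
#'   round(onset_s/tr_s) + frames_for_duration(duration_s, tr_s) + pad_after)`
#' (0-based, half-open). In `"strict"` mode the padded interval must lie
#' inside the run; `"clamp"` truncates to the run and records the actual
#' span.
#'
#' @param run An `fmri_run`.
#' @param onset_s Block onset in seconds.
#' @param duration_s Block duration in seconds.
#' @param pad_before,pad_after Extra frames on each side (non-negative
#'   integers). Padding is a user choice, not a constant of the package.
#' @param label Optional condition label carried by the clip.
#' @param mode `"strict"` (default) or `"clamp"`.
#' @return An [new_clip()] whose `source_span` records the frames taken.
#' @export
extract_clip <- function(run, onset_s, duration_s, pad_before = 0L,
                         pad_after = 0L, label = NULL,
                         mode = c("strict", "clamp")) {
  stopifnot(inherits(run, "fmri_run"))
  mode <- match.arg(mode)
  if (!is_count(pad_before) || !is_count(pad_after))
    stop_fc("pad_before and pad_after must be non-negative integers")
  onset_f <- as.integer(round_half_up(onset_s / run$tr_s))
  lo <- onset_f - as.integer(pad_before)
  hi <- onset_f + frames_for_duration(duration_s, run$tr_s) +
    as.integer(pad_after)
  nt <- n_frames(run)
  if (lo < 0L || hi > nt) {
    if (mode == "strict")
      stop_fc("padded clip frames [", lo, ", ", hi, ") fall outside the run ",
              "[0, ", nt, "); use mode = \"clamp\" to truncate")
    lo <- max(lo, 0L)
    hi <- min(hi, nt)
  }
  if (hi <= lo) stop_fc("clip is empty after clamping")
  new_clip(run$data[(lo + 1L):hi, , , , drop = FALSE], tr_s = run$tr_s,
           subject_id = run$subject_id, label = label,
           source_span = c(lo, hi))
}
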