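#' Configuration of the temporal pretext task
#'
#' Controls how a clip is divided into (beginning, middle, end) segments of
#' `k` frames each. With `overlap = 0` the segments are pairwise disjoint,
#' each placed inside its third of the clip. With `overlap = o > 0` (the
#' overlapped ablation variant) the middle segment overlaps the beginning
#' and the end by exactly `o` frames, which forces the chain
#' `begin = a`, `middle = a + k - o`, `end = a + 2(k - o)`; the remaining
#' freedom is the global offset `a`. `2*overlap <= k` keeps beginning and
#' end disjoint.
#'
#' @param k Frames per segment (>= 1). Typical values: 9, 12, 15.
#' @param overlap Overlap frames `o` between the middle segment and each
#'   neighbour; 0 = disjoint mode.
#' @param placement `"random"` (training: uniform over valid offsets) or
#'   `"centered"` (deterministic, for evaluation).
#' @param normalize Per-clip normalisation before segmentation: `"voxel"`
#'   (default; [normalize_voxelwise()]), `"global"` ([normalize_clip()]) or
#'   `"none"`. `TRUE`/`FALSE` are accepted as `"voxel"`/`"none"`.
#' @return An object of class `pretext_config`.
#' @export
pretext_config <- function(k, overlap = 0L, placement = c("random", "centered"),
                           normalize = "voxel") {
  placement <- match.arg(placement)
  if (!is_count(k) || k < 1) stop_fc("k must be a positive integer")
  if (!is_count(overlap) || overlap >= k)
    stop_fc("overlap must satisfy 0 <= overlap < k")
  if (2 * overlap > k)
    stop_fc("2*overlap must be <= k so that beginning and end stay disjoint")
  nfun <- normalizer(normalize)   # validates
  normalize <- if (isTRUE(normalize)) "voxel"
               else if (identical(normalize, FALSE)) "none" else normalize
  structure(list(k = as.integer(k), overlap = as.integer(overlap),
                 placement = placement, normalize = normalize),
            class = "pretext_config")
}

# Minimum clip length for a config: 3k disjoint, 3k - 2o overlapped.
min_clip_frames <- function(cfg) 3L * cfg$k - 2L * cfg$overlap

#' Cut a clip into a (beginning, middle, end) segment triplet
#'
#' Disjoint mode partitions the `T` clip frames into three contiguous thirds
#' and places one `k`-frame window inside each third (centered, or at a
#' uniformly random valid offset). Overlapped mode places the rigid chain of
#' three windows with stride `k - o` at a centered or random global offset.
#'
#' @param clip An `fmri_clip` with at least `3k - 2*overlap` frames.
#' @param cfg A [pretext_config()].
#' @param seed Optional integer seed for random placement; `NULL` draws from
#'   the current RNG stream.
#' @return An object of class `segment_triplet` with fields `beginning`,
#'   `middle`, `end` (4-D arrays of `k` frames each) and `spans` (list of
#'   three 0-based half-open frame intervals into the clip).
#' @export
make_triplet <- function(clip, cfg, seed = NULL) {
  stopifnot(inherits(clip, "fmri_clip"), inherits(cfg, "pretext_config"))
  nt <- n_frames(clip)
  need <- min_clip_frames(cfg)
  if (nt < need)
    stop_fc("clip has T = ", nt, " frames but k = ", cfg$k, ", overlap = ",
            cfg$overlap, " requires at least ", need)
  starts <- with_seed(seed, triplet_starts(nt, cfg))
  nfun <- normalizer(cfg$normalize)
  dat <- if (is.null(nfun)) clip$data else nfun(clip$data)
  seg <- function(s) dat[(s + 1L):(s + cfg$k), , , , drop = FALSE]
  structure(
    list(beginning = seg(starts[1]), middle = seg(starts[2]),
         end = seg(starts[3]),
         spans = lapply(starts, function(s) c(s, s + cfg$k)),
         k = cfg$k, overlap = cfg$overlap),
    class = "segment_triplet"
  )
}

# Start frames (0-based) of the three segments within a T-frame clip.
triplet_starts <- function(nt, cfg) {
  k <- cfg$k; o <- cfg$overlap
  pick <- function(lo, hi) {  # integer offset in [lo, hi]
    if (cfg$placement == "centered") lo + (hi - lo) %/% 2L
    else lo + sample.int(hi - lo + 1L, 1L) - 1L
  }
  if (o == 0L) {
    b1 <- nt %/% 3L
    b2 <- (2L * nt) %/% 3L
    bounds <- list(c(0L, b1), c(b1, b2), c(b2, nt))
    vapply(bounds, function(th) pick(th[1], th[2] - k), integer(1))
  } else {
    len <- 3L * k - 2L * o
    a <- pick(0L, nt - len)
    c(a, a + k - o, a + 2L * (k - o))
  }
}

#' Per-clip global z-scoring
#'
#' Centers and scales a clip (or any array) to zero mean and unit standard
#' deviation over all voxels and frames jointly, making the encoder input
#' scale-free. A constant array maps to all zeros.
#'
#' @param data Numeric array.
#' @return Array of the same shape.
#' @export
normalize_clip <- function(data) {
  mu <- mean(data)
  s <- sd(as.vector(data))
  if (!is.finite(s) || s < 1e-12) {
    data[] <- 0
    return(data)
  }
  (data - mu) / s
}

#' Per-voxel temporal demeaning of a clip
#'
#' Subtracts each voxel's temporal mean, then rescales the whole clip to
#' unit global standard deviation (`scale = "global"`, the default) or
#' z-scores each voxel individually (`scale = "voxel"`). Unlike the global
#' z-score, demeaning removes static anatomy (baseline, bias fields)
#' entirely: in raw fMRI units the inside/outside-brain intensity step
#' dwarfs any task response, and a global z-score leaves the response at
#' ~1% contrast. The default global rescaling preserves *relative*
#' response amplitudes across voxels (how strongly and extensively a task
#' responds), which per-voxel scaling would flatten to unit variance
#' everywhere. A constant clip maps to zeros.
#'
#' @param data 4-D numeric array `(t, x, y, z)` with at least 2 frames.
#' @param scale `"global"` (one sd for the whole demeaned clip) or
#'   `"voxel"` (each voxel to unit temporal variance).
#' @return Array of the same shape.
#' @export
normalize_voxelwise <- function(data, scale = c("global", "voxel")) {
  scale <- match.arg(scale)
  d <- dim(data)
  if (is.null(d) || length(d) != 4L)
    stop_fc("expected a 4-D (t, x, y, z) array")
  if (d[1] < 2L) stop_fc("need at least 2 frames to standardise over time")
  M <- matrix(data, nrow = d[1])
  mu <- colMeans(M)
  M <- M - rep(mu, each = d[1])
  if (scale == "voxel") {
    sdv <- sqrt(colMeans(M * M))
    M <- M / rep(pmax(sdv, 1e-12), each = d[1])
    M[, sdv < 1e-8] <- 0
  } else {
    s <- sd(as.vector(M))
    M <- if (is.finite(s) && s > 1e-12) M / s else M * 0
  }
  dim(M) <- d
  M
}

# Resolve a normalisation setting (TRUE/FALSE or mode string) to a
# function or NULL.
normalizer <- function(normalize) {
  if (isTRUE(normalize)) normalize <- "voxel"
  if (identical(normalize, FALSE)) normalize <- "none"
  switch(normalize,
         voxel = normalize_voxelwise,
         voxel_z = function(x) normalize_voxelwise(x, scale = "voxel"),
         global = normalize_clip,
         none = NULL,
         stop_fc("normalize must be TRUE, FALSE, \"voxel\", \"voxel_z\", ",
                 "\"global\" or \"none\""))
}

#' Shuffled per-epoch batches of clip indices
#'
#' @param n Number of clips.
#' @param batch_size Batch size; the final partial batch is kept.
#' @param seed Optional seed for the shuffle.
#' @return List of integer index vectors covering `1:n` exactly once.
#' @export
epoch_batches <- function(n, batch_size, seed = NULL) {
  if (!is_count(n) || n < 1) stop_fc("n must be a positive integer")
  if (!is_count(batch_size) || batch_size < 1)
    stop_fc("batch_size must be a positive integer")
  perm <- with_seed(seed, sample.int(n))
  split(perm, ceiling(seq_along(perm) / batch_size))
}

#' Materialise one epoch of segment-triplet batches
#'
#' Visits every clip exactly once in a seeded shuffle and returns triplets
#' grouped into batches; the final partial batch is yielded. Fails fast if
#' any clip is too short for the configuration.
#'
#' @param clips List of `fmri_clip` objects.
#' @param cfg A [pretext_config()].
#' @param batch_size Triplets per batch.
#' @param seed Optional seed controlling both the shuffle and the random
#'   segment placements.
#' @return List of batches; each batch is a list of `segment_triplet`s with
#'   the source clip index attached as attribute `clip_index`.
#' @export
triplet_batches <- function(clips, cfg, batch_size, seed = NULL) {
  stopifnot(inherits(cfg, "pretext_config"))
  need <- min_clip_frames(cfg)
  lens <- vapply(clips, n_frames, integer(1))
  if (any(lens < need))
    stop_fc("clip(s) ", paste(which(lens < need), collapse = ", "),
            " are shorter than the required ", need, " frames")
  with_seed(seed, {
    idx_batches <- epoch_batches(length(clips), batch_size)
    lapply(idx_batches, function(ix) {
      lapply(ix, function(i) {
        tr <- make_triplet(clips[[i]], cfg)
        attr(tr, "clip_index") <- i
        tr
      })
    })
  })
}

#' Correlation of segment pair summaries within a triplet
#'
#' Measures how similar two segments of a triplet are before any encoding:
#' each segment is averaged over its `k` frames and the two resulting
#' volumes are correlated across voxels. On temporally autocorrelated data
#' the middle-end (adjacent) value is expected to exceed the beginning-end
#' (distant) value -- the premise that temporally close activity is more
#' alike, which the contrastive objective builds on.
#'
#' @param triplet A `segment_triplet`.
#' @return Named numeric vector `c(beginning_end = , middle_end = )`.
#' @export
premise_correlations <- function(triplet) {
  stopifnot(inherits(triplet, "segment_triplet"))
  avg <- function(seg) as.vector(colMeans(matrix(seg, nrow = dim(seg)[1])))
  b <- avg(triplet$beginning); m <- avg(triplet$middle); e <- avg(triplet$end)
  c(beginning_end = cor(b, e), middle_end = cor(m, e))
}

#' @export
print.segment_triplet <- function(x, ...) {
  sp <- vapply(x$spans, function(s) sprintf("[%d,%d)", s[1], s[2]),
               character(1))
  cat(sprintf("<segment_triplet> k = %d, overlap = %d, spans %s\n",
              x$k, x$overlap, paste(sp, collapse = " ")))
  invisible(x)
}
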