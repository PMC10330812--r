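#' Specification of the block-design fMRI simulator
#'
#' The simulator emulates the statistical structure the pretext task relies
#' on in real task fMRI: a block paradigm whose boxcar is convolved with a
#' double-gamma HRF, expressed in a task-specific smooth spatial pattern
#' shared across subjects up to a per-subject gain, on top of spatially
#' smoothed AR(1) noise, low-frequency polynomial drift and a baseline of
#' 100 (conventional fMRI scaling). Every run is a pure function of the
#' spec, the subject index and the task name.
#'
#' Blocks are centred inside their block+rest cycle, so half the rest
#' period precedes and half follows each block -- clip padding up to half
#' the rest duration never leaves the run.
#'
#' @param spatial_shape Length-3 integer vector of voxel extents.
#' @param tr_s Repetition time in seconds.
#' @param n_subjects Number of simulated subjects.
#' @param task_names Character vector of task names (one condition each).
#' @param blocks_per_run Task blocks per run.
#' @param block_duration_s,rest_duration_s Block and rest durations (s).
#' @param amplitude Task signal scale relative to the noise sd.
#' @param ar_rho Lag-1 autoregressive coefficient of the noise, in [0, 1).
#' @param noise_sd Marginal standard deviation of the noise.
#' @param noise_smooth_sd Spatial Gaussian sd (voxels) applied to the noise;
#'   mixing equal-rho AR(1) series preserves the lag-1 coefficient, and the
#'   noise is rescaled back to `noise_sd` afterwards. 0 disables smoothing.
#' @param drift_order Polynomial drift order; 0 disables drift.
#' @param pattern_smoothness Base spatial Gaussian sd (voxels) of the task
#'   activation patterns; each task uses a fixed task-specific multiple in
#'   [0.55, 1.45] of it, so topographies differ between tasks in spatial
#'   granularity as well as location.
#' @param subject_gain_sd Sd of the per-subject multiplicative gain around 1.
#' @param seed Master seed; all per-subject/per-task seeds derive from it.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(spatial_shape = c(16L, 16L, 16L), tr_s = 1.0,
                     n_subjects = 3L, task_names = c("taskA", "taskB"),
                     blocks_per_run = 8L, block_duration_s = 16,
                     rest_duration_s = 10, amplitude = 1.0, ar_rho = 0.4,
                     noise_sd = 1.0, noise_smooth_sd = 0.5, drift_order = 2L,
                     pattern_smoothness = 1.5, subject_gain_sd = 0.1,
                     seed = 1L) {
  if (length(spatial_shape) != 3L || any(spatial_shape < 1))
    stop_fc("spatial_shape must be three positive extents")
  if (tr_s <= 0) stop_fc("tr_s must be positive")
  if (ar_rho < 0 || ar_rho >= 1) stop_fc("ar_rho must lie in [0, 1)")
  if (amplitude < 0) stop_fc("amplitude must be >= 0")
  if (block_duration_s <= 0 || rest_duration_s <= 0)
    stop_fc("durations must be positive")
  if (!is_count(drift_order)) stop_fc("drift_order must be >= 0")
  structure(
    list(spatial_shape = as.integer(spatial_shape), tr_s = tr_s,
         n_subjects = as.integer(n_subjects),
         task_names = as.character(task_names),
         blocks_per_run = as.integer(blocks_per_run),
         block_duration_s = block_duration_s,
         rest_duration_s = rest_duration_s, amplitude = amplitude,
         ar_rho = ar_rho, noise_sd = noise_sd,
         noise_smooth_sd = noise_smooth_sd,
         drift_order = as.integer(drift_order),
         pattern_smoothness = pattern_smoothness,
         subject_gain_sd = subject_gain_sd, seed = as.integer(seed)),
    class = "sim_spec"
  )
}

#' Double-gamma hemodynamic response function
#'
#' Canonical difference of gamma densities (shapes 6 and 16, unit rate,
#' undershoot ratio 1/6), peaking near 5 s with an undershoot around 15 s,
#' sampled on `t_s` (default: one TR grid over `duration_s` seconds) and
#' scaled so the peak equals 1.
#'
#' @param tr_s Sampling interval in seconds.
#' @param t_s Optional explicit time grid (seconds); overrides `tr_s`
#'   sampling.
#' @param duration_s Kernel length in seconds.
#' @return Numeric kernel with attribute `t_s` (the grid).
#' @export
double_gamma_hrf <- function(tr_s, t_s = NULL, duration_s = 32) {
  if (is.null(t_s)) {
    if (tr_s <= 0) stop_fc("tr_s must be positive")
    t_s <- seq(0, duration_s, by = tr_s)
  }
  h <- dgamma(t_s, shape = 6, rate = 1) - dgamma(t_s, shape = 16, rate = 1) / 6
  h <- h / max(h)
  attr(h, "t_s") <- t_s
  h
}

# Separable Gaussian smoothing of a 3-D array (kernel truncated at 3 sd,
# edge-renormalised). sd in voxels.
gaussian_smooth3d <- function(arr, sd_vox) {
  if (sd_vox <= 0) return(arr)
  d <- dim(arr)
  r <- max(1L, ceiling(3 * sd_vox))
  w <- dnorm(-r:r, sd = sd_vox)
  smooth_axis <- function(n) {
    S <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- pmax(1L, pmin(n, i + (-r:r)))
      for (t in seq_along(j)) S[i, j[t]] <- S[i, j[t]] + w[t]
    }
    S / rowSums(S)
  }
  Sx <- smooth_axis(d[1]); Sy <- smooth_axis(d[2]); Sz <- smooth_axis(d[3])
  m <- Sx %*% matrix(arr, d[1])                       # along x
  arr <- array(m, d)
  arr <- aperm(array(Sy %*% matrix(aperm(arr, c(2, 1, 3)), d[2]),
                     d[c(2, 1, 3)]), c(2, 1, 3))      # along y
  aperm(array(Sz %*% matrix(aperm(arr, c(3, 1, 2)), d[3]),
              d[c(3, 1, 2)]), c(2, 3, 1))             # along z
}

# Task-specific activation pattern: smoothed Gaussian random field,
# thresholded, rescaled to [0, 1]. Tasks differ not only in where the
# field lands (two equal-statistics fields differ only by location, which
# a translation-invariant decoder cannot see) but also in granularity
# (texture scale, a fixed spread of 0.55-1.45 around pattern_smoothness)
# and in extent (threshold between 0.6 and 1.4 field sds, i.e. broad weak
# vs focal strong topographies) -- mirroring how real task contrasts
# differ in smoothness and spatial extent across cognitive domains.
task_texture_scale <- function(tix) 0.55 + 0.9 * (((tix * 5) %% 9) / 8)

task_threshold <- function(tix) 0.6 + 0.8 * ((((tix - 1) * 5) %% 8) / 7)

task_pattern <- function(spec, task) {
  tix <- match(task, spec$task_names)
  if (is.na(tix)) stop_fc("unknown task: ", task)
  with_seed(derive_seed(spec$seed, 1L, tix), {
    g <- array(rnorm(prod(spec$spatial_shape)), dim = spec$spatial_shape)
    s <- gaussian_smooth3d(g, spec$pattern_smoothness * task_texture_scale(tix))
    s <- (s - mean(s)) / sd(as.vector(s))
    # saturating ramp: near-binary support with a soft half-sd edge, so a
    # task's total activation mass scales with its extent
    pmin(1, pmax(s - task_threshold(tix), 0) / 0.5)
  })
}

subject_gain <- function(spec, subject) {
  with_seed(derive_seed(spec$seed, 2L, subject),
            1 + rnorm(1) * spec$subject_gain_sd)
}

# Ellipsoidal brain mask covering ~90% of each half-extent.
sim_brain_mask <- function(shape) {
  ax <- lapply(shape, function(n) (seq_len(n) - (n + 1) / 2) / (0.9 * n / 2))
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  r2 <= 1
}

run_timing <- function(spec) {
  block_f <- frames_for_duration(spec$block_duration_s, spec$tr_s)
  rest_f <- frames_for_duration(spec$rest_duration_s, spec$tr_s)
  cycle_s <- spec$block_duration_s + spec$rest_duration_s
  onsets <- (seq_len(spec$blocks_per_run) - 1) * cycle_s +
    spec$rest_duration_s / 2
  list(n_frames = spec$blocks_per_run * (block_f + rest_f),
       onsets_s = onsets, block_f = block_f)
}

#' Simulate one subject's run for one task
#'
#' See [sim_spec()] for the generative model. The run and its event table
#' are a pure function of `(spec, subject, task)`.
#'
#' @param spec A [sim_spec()].
#' @param subject Subject index in `1:n_subjects`.
#' @param task Task name from `spec$task_names`.
#' @return List with `run` (an `fmri_run` with brain mask) and `events`
#'   (block timing `data.frame`).
#' @export
generate_run <- function(spec, subject = 1L, task = spec$task_names[1]) {
  stopifnot(inherits(spec, "sim_spec"))
  tix <- match(task, spec$task_names)
  if (is.na(tix)) stop_fc("unknown task: ", task)
  tm <- run_timing(spec)
  nt <- tm$n_frames
  nv <- prod(spec$spatial_shape)

  # HRF-convolved boxcar, peak-normalised regressor
  box <- numeric(nt)
  for (o in tm$onsets_s) {
    lo <- round_half_up(o / spec$tr_s)
    box[(lo + 1):min(nt, lo + tm$block_f)] <- 1
  }
  h <- double_gamma_hrf(spec$tr_s)
  reg <- convolve(box, rev(h), type = "open")[seq_len(nt)]
  if (max(reg) > 0) reg <- reg / max(reg)

  pattern <- task_pattern(spec, task)
  gain <- subject_gain(spec, subject)
  mask <- sim_brain_mask(spec$spatial_shape)
  pattern <- pattern * mask

  with_seed(derive_seed(spec$seed, 3L, subject, tix), {
    # AR(1) noise, stationary start, marginal sd = noise_sd before smoothing
    innov_sd <- spec$noise_sd * sqrt(1 - spec$ar_rho^2)
    eps <- matrix(rnorm(nt * nv, sd = innov_sd), nt, nv)
    eps[1, ] <- rnorm(nv, sd = spec$noise_sd)
    noise <- eps
    for (t in 2:nt) noise[t, ] <- spec$ar_rho * noise[t - 1, ] + eps[t, ]
    if (spec$noise_smooth_sd > 0) {
      for (t in seq_len(nt)) {
        noise[t, ] <- as.vector(
          gaussian_smooth3d(array(noise[t, ], spec$spatial_shape),
                            spec$noise_smooth_sd))
      }
      noise <- noise * (spec$noise_sd / sd(as.vector(noise)))
    }

    # low-frequency polynomial drift, per-voxel random coefficients
    drift <- 0
    if (spec$drift_order > 0) {
      basis <- poly(seq_len(nt), degree = spec$drift_order) * sqrt(nt)
      coef <- matrix(rnorm(spec$drift_order * nv, sd = 0.5 * spec$noise_sd),
                     spec$drift_order, nv)
      drift <- basis %*% coef
    }

    signal <- spec$amplitude * gain * spec$noise_sd *
      (reg %o% as.vector(pattern))
    baseline <- matrix(100 * as.vector(mask), nt, nv, byrow = TRUE)
    dat <- baseline + signal + noise + if (is.matrix(drift))
      drift * matrix(as.vector(mask), nt, nv, byrow = TRUE) else 0
    dim(dat) <- c(nt, spec$spatial_shape)

    events <- data.frame(onset = tm$onsets_s,
                         duration = spec$block_duration_s,
                         condition = task)
    list(run = new_run(dat, tr_s = spec$tr_s,
                       subject_id = sprintf("sub-%02d", subject),
                       brain_mask = mask),
         events = events)
  })
}

#' Simulate a labelled multi-subject, multi-task clip collection
#'
#' Generates one run per subject and task, extracts one clip per block
#' (block frames plus the requested padding) via [extract_clip()], and
#' returns the clips together with the generating ground truth.
#'
#' @param spec A [sim_spec()].
#' @param pad_before,pad_after Clip padding in frames; must not exceed half
#'   the rest duration.
#' @param subjects Subject indices to generate (default all).
#' @param tasks Task names to generate (default all).
#' @return List with `clips` (labelled `fmri_clip`s), `truth` (per-task
#'   patterns, per-subject gains, event tables) and `spec`.
#' @export
generate_dataset <- function(spec, pad_before = 3L, pad_after = 3L,
                             subjects = seq_len(spec$n_subjects),
                             tasks = spec$task_names) {
  stopifnot(inherits(spec, "sim_spec"))
  clips <- list()
  events <- list()
  for (s in subjects) {
    for (task in tasks) {
      g <- generate_run(spec, s, task)
      events[[paste0(g$run$subject_id, "_", task)]] <- g$events
      for (r in seq_len(nrow(g$events))) {
        clips[[length(clips) + 1L]] <-
          extract_clip(g$run, g$events$onset[r], g$events$duration[r],
                       pad_before = pad_before, pad_after = pad_after,
                       label = task)
      }
    }
  }
  truth <- list(
    patterns = setNames(lapply(tasks, function(t) task_pattern(spec, t)),
                        tasks),
    gains = setNames(vapply(subjects, function(s) subject_gain(spec, s),
                            numeric(1)),
                     sprintf("sub-%02d", subjects)),
    events = events)
  list(clips = clips, truth = truth, spec = spec)
}

#' Write a simulated dataset to disk
#'
#' One NIfTI run and one events TSV per subject and task, plus a JSON
#' ground-truth sidecar (per-task patterns flattened, per-subject gains).
#'
#' @param spec A [sim_spec()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(spec, dir) {
  stopifnot(inherits(spec, "sim_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in seq_len(spec$n_subjects)) {
    for (task in spec$task_names) {
      g <- generate_run(spec, s, task)
      stem <- file.path(dir, sprintf("%s_task-%s", g$run$subject_id, task))
      save_run(g$run, paste0(stem, "_bold.nii.gz"))
      write_events(g$events, paste0(stem, "_events.tsv"))
    }
  }
  truth <- list(
    spec = unclass(spec),
    gains = vapply(seq_len(spec$n_subjects),
                   function(s) subject_gain(spec, s), numeric(1)),
    patterns = lapply(spec$task_names,
                      function(t) as.vector(task_pattern(spec, t))))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
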