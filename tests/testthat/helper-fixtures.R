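# Shared fixtures, all generated in code at test time.

# A small run with reproducible random content.
tiny_run <- function(nt = 20, shape = c(10, 11, 12), tr_s = 1, seed = 42,
                     subject_id = "sub-01") {
  arr <- fmricontrast:::with_seed(seed,
    array(rnorm(nt * prod(shape)), c(nt, shape)))
  new_run(arr, tr_s = tr_s, subject_id = subject_id)
}

tiny_clip <- function(nt = 21, shape = c(8, 8, 8), tr_s = 1, seed = 7,
                      label = NULL, subject_id = "sub-01") {
  arr <- fmricontrast:::with_seed(seed,
    array(rnorm(nt * prod(shape)), c(nt, shape)))
  new_clip(arr, tr_s = tr_s, label = label, subject_id = subject_id)
}

# Tiny encoder specs: cheap enough for exhaustive checks.
tiny_espec <- function(k = 3, seed = 2, stem_stride = 2L) {
  encoder_spec(k = k, base_channels = 3, stage_channels = c(3, 4, 4, 5),
               proj_hidden = 6, contrast_dim = 4, stem_stride = stem_stride,
               seed = seed)
}

# The small-but-trainable encoder used for the training-based checks.
desk_espec <- function(k = 7, seed = 1) {
  encoder_spec(k = k, base_channels = 4, stage_channels = c(4, 8, 16, 16),
               proj_hidden = 16, contrast_dim = 8, seed = seed)
}

# A two-class dataset that is separable by construction: large-amplitude
# task patterns differing strongly in spatial extent (broad vs focal
# topographies), with rests long enough for the HRF to relax between
# blocks so clips carry real task-vs-baseline contrast.
separable_dataset <- function(n_subjects = 6, blocks = 4, amplitude = 10,
                              seed = 33) {
  sp <- sim_spec(n_subjects = n_subjects, task_names = c("faces", "houses"),
                 blocks_per_run = blocks, amplitude = amplitude,
                 rest_duration_s = 20, seed = seed)
  generate_dataset(sp)
}

expect_grad_close <- function(analytic, fd, tol_abs = 1e-4, tol_rel = 1e-3) {
  ok <- abs(analytic - fd) < tol_abs |
    abs(analytic - fd) / pmax(abs(analytic) + abs(fd), 1e-8) < tol_rel
  expect_true(all(ok))
}
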