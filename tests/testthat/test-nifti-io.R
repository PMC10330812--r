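test_that("NIfTI roundtrip preserves data, TR and affine", {
  run <- tiny_run(nt = 30, shape = c(8, 9, 10), tr_s = 0.72, seed = 1)
  run$affine <- matrix(c(2, 0, 0, 0, 0, 2, 0, 0, 0, 0, 2, 0,
                         -10, -20, -30, 1), 4, 4)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  save_run(run, f)
  back <- load_run(f, subject_id = "sub-01")
  expect_identical(dim(back$data), c(30L, 8L, 9L, 10L))
  expect_equal(back$data, run$data, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$tr_s, 0.72, tolerance = 1e-6)
  expect_equal(back$affine, run$affine, tolerance = 1e-5)
  # integer data roundtrips bit-exactly
  run2 <- new_run(array(as.double(sample.int(100, 5 * 6^3, TRUE)),
                        c(5, 6, 6, 6)), tr_s = 2)
  f2 <- withr::local_tempfile(fileext = ".nii.gz")
  save_run(run2, f2)
  expect_identical(load_run(f2)$data, run2$data)
})

test_that("load_run rejects 3-D volumes and honours TR override", {
  f <- withr::local_tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 4))), f)
  expect_error(load_run(f), "4-D")
  run <- tiny_run(nt = 6, shape = c(8, 8, 8), tr_s = 1.5)
  f2 <- withr::local_tempfile(fileext = ".nii.gz")
  save_run(run, f2)
  expect_equal(load_run(f2, tr_s = 3)$tr_s, 3)
})

test_that("frames_for_duration rounds halves away from zero", {
  expect_identical(frames_for_duration(0, 1), 0L)
  expect_identical(frames_for_duration(1.5, 1), 2L)
  expect_identical(frames_for_duration(2.5, 1), 3L)
  expect_identical(frames_for_duration(17.9, 2), 9L)
  expect_error(frames_for_duration(-1, 1), ">= 0")
  expect_error(frames_for_duration(1, 0), "positive")
})

test_that("compute_bbox matches a brute-force min/max oracle", {
  full <- compute_bbox(array(TRUE, c(5, 6, 7)))
  expect_identical(bbox_size(full), c(5L, 6L, 7L))
  single <- array(FALSE, c(6, 6, 6)); single[3, 4, 5] <- TRUE
  bb <- compute_bbox(single)
  expect_identical(bb$lo, c(2L, 3L, 4L))
  expect_identical(bb$hi, c(3L, 4L, 5L))
  two <- array(FALSE, c(7, 8, 9)); two[1, 1, 1] <- TRUE; two[5, 6, 7] <- TRUE
  expect_identical(bbox_size(compute_bbox(two)), c(5L, 6L, 7L))
  # random masks against an oracle built from the raw coordinates
  set.seed(5)
  for (i in 1:20) {
    m <- array(runif(4 * 5 * 6) < 0.2, c(4, 5, 6))
    if (!any(m)) next
    bb <- compute_bbox(m)
    idx <- which(m, arr.ind = TRUE)
    expect_identical(bb$lo, as.integer(apply(idx, 2, min) - 1L))
    expect_identical(bb$hi, as.integer(apply(idx, 2, max)))
  }
  expect_error(compute_bbox(array(FALSE, c(3, 3, 3))), "empty")
})

test_that("crop restricts space, preserves values and is idempotent", {
  run <- tiny_run(nt = 20, shape = c(10, 11, 12))
  full <- new_bbox(c(0, 0, 0), c(10, 11, 12))
  expect_identical(crop(run, full)$data, run$data)
  bb <- new_bbox(c(1, 2, 3), c(5, 7, 9))   # sizes 4, 5, 6
  out <- crop(run, bb)
  expect_identical(dim(out$data), c(20L, 4L, 5L, 6L))
  # exhaustive elementwise oracle: out[t,i,j,k] == in[t, 1+i, 2+j, 3+k]
  expect_identical(out$data,
                   run$data[, 2:5, 3:7, 4:9, drop = FALSE])
  again <- crop(out, new_bbox(c(0, 0, 0), c(4, 5, 6)))
  expect_identical(again$data, out$data)
  expect_error(crop(run, new_bbox(c(0, 0, 0), c(11, 11, 12))), "exceeds")
  # cropping a mask to its own bbox fills the cropped extent
  m <- array(FALSE, c(10, 11, 12)); m[3:6, 2:9, 5:5] <- TRUE
  bbm <- compute_bbox(m)
  expect_identical(bbox_size(compute_bbox(crop(m, bbm))),
                   bbox_size(bbm))
})

test_that("apply_network_mask zeroes outside voxels and crops to the ROI", {
  run <- tiny_run(nt = 8, shape = c(9, 9, 9))
  all_in <- array(TRUE, c(9, 9, 9))
  expect_identical(apply_network_mask(run, all_in)$data, run$data)
  one <- array(FALSE, c(9, 9, 9)); one[4, 5, 6] <- TRUE
  out1 <- apply_network_mask(run, one)
  expect_identical(dim(out1$data), c(8L, 1L, 1L, 1L))
  expect_identical(as.vector(out1$data), as.vector(run$data[, 4, 5, 6]))
  set.seed(2)
  m <- array(runif(9^3) < 0.3, c(9, 9, 9))
  out <- apply_network_mask(run, m)
  bb <- compute_bbox(m)
  mc <- crop(m, bb)
  rc <- crop(run, bb)
  for (t in c(1L, 5L)) {
    expect_equal(out$data[t, , , ], rc$data[t, , , ] * mc,
                 ignore_attr = TRUE)
  }
  expect_error(apply_network_mask(run, array(TRUE, c(3, 3, 3))), "shape")
})

test_that("extract_clip frame arithmetic follows the padding formula", {
  run <- tiny_run(nt = 40, shape = c(8, 8, 8), tr_s = 1)
  cl <- extract_clip(run, onset_s = 10, duration_s = 18, pad_before = 3,
                     pad_after = 3, label = "cond")
  expect_identical(cl$source_span, c(7L, 31L))
  expect_identical(n_frames(cl), 24L)
  expect_identical(cl$label, "cond")
  expect_identical(cl$data, run$data[8:31, , , , drop = FALSE])
  whole <- extract_clip(run, 0, 40)
  expect_identical(whole$data, run$data)
  expect_error(extract_clip(run, 0, 10, pad_before = 4), "outside the run")
  clamped <- extract_clip(run, 0, 10, pad_before = 4, mode = "clamp")
  expect_identical(clamped$source_span, c(0L, 10L))
  # property: strict-mode clip length is pads + block frames
  set.seed(11)
  for (i in 1:25) {
    tr <- runif(1, 0.5, 2.5)
    r <- new_run(array(0, c(60, 8, 8, 8)), tr_s = tr)
    dur <- runif(1, 3, 20)
    pb <- sample(0:3, 1); pa <- sample(0:3, 1)
    onset <- runif(1, (pb + 1) * tr, 20 * tr)
    nf <- frames_for_duration(dur, tr)
    if (round(onset / tr) + nf + pa > 60) next
    cl <- extract_clip(r, onset, dur, pb, pa)
    expect_identical(n_frames(cl), as.integer(pb + nf + pa))
  }
})

test_that("event tables validate, sort and roundtrip as TSV", {
  ev <- data.frame(onset = c(30, 0, 15), duration = c(5, 5, 5),
                   condition = c("c", "a", "b"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_events(ev, f)
  expect_identical(readLines(f)[1], "onset\tduration\tcondition")
  back <- read_events(f)
  expect_identical(back$condition, c("a", "b", "c"))   # sorted by onset
  expect_equal(back$onset, c(0, 15, 30))
  expect_error(write_events(data.frame(onset = 1, duration = 0,
                                       condition = "x"), f), "positive")
  expect_error(write_events(data.frame(onset = -1, duration = 1,
                                       condition = "x"), f), ">= 0")
  expect_error(read_events({
    f2 <- withr::local_tempfile(fileext = ".tsv")
    writeLines("a\tb\n1\t2", f2); f2
  }), "columns")
})

test_that("masks load as logical volumes and parcel labels select networks", {
  lab <- array(0L, c(6, 6, 6)); lab[1:2, , ] <- 1L; lab[5:6, , ] <- 2L
  f <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(lab), f)
  m <- load_mask(f)
  expect_type(m, "logical")
  expect_identical(sum(m), sum(lab != 0))
  labs <- load_mask(f, labels = TRUE)
  expect_identical(network_mask(labs, 2L), lab == 2L)
})
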