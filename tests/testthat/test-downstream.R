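test_that("window sampling covers valid offsets and centers for evaluation", {
  cl <- tiny_clip(nt = 9, shape = c(4, 4, 4), seed = 2)
  w <- sample_window(cl, 9)
  expect_identical(w, cl$data)               # only one placement
  expect_identical(sample_window(cl, 5, mode = "centered"),
                   cl$data[3:7, , , , drop = FALSE])  # offset (9-5)%/%2 = 2
  offs <- replicate(400, {
    w <- sample_window(cl, 5, mode = "random")
    which(vapply(0:4, function(o)
      identical(w, cl$data[(o + 1):(o + 5), , , , drop = FALSE]),
      logical(1))) - 1L
  })
  expect_setequal(unique(offs), 0:4)         # every offset attained
  tab <- table(offs)
  expect_true(all(tab > 400 / 5 * 0.4))      # roughly uniform
  expect_error(sample_window(cl, 10), "shorter")
})

test_that("attaching a classifier keeps or redraws weights as requested", {
  es <- tiny_espec(k = 3, seed = 4)
  enc <- build_encoder(es)
  m_pre <- attach_classifier(enc, 3)
  m_rnd <- attach_classifier(enc, 3, init = "random", seed = 99)
  expect_null(m_pre$params[["h1.W"]])        # projection head dropped
  expect_identical(dim(m_pre$params$cls.W), c(3L, es$feature_dim))
  expect_identical(m_pre$params$t.W, enc$params$t.W)
  expect_false(identical(m_rnd$params$t.W, enc$params$t.W))
  expect_identical(dim(m_rnd$params$t.W), dim(enc$params$t.W))
  # attaching twice from one checkpoint gives identical initial logits
  x <- tiny_clip(nt = 5, shape = c(8, 8, 8), seed = 5)
  p1 <- predict_clip(m_pre, x)
  p2 <- predict_clip(attach_classifier(enc, 3), x)
  expect_identical(p1, p2)
  expect_equal(sum(p1), 1, tolerance = 1e-6)
  expect_true(all(p1 >= 0))
  expect_error(attach_classifier(enc, 1), "n_classes")
})

test_that("the plateau schedule drops the lr exactly after patience epochs", {
  ds <- separable_dataset(n_subjects = 3, blocks = 2)
  d <- labeled_dataset(ds$clips)
  tr <- fmricontrast:::subset_subjects(d, c("sub-01", "sub-02"))
  va <- fmricontrast:::subset_subjects(d, "sub-03")
  es <- tiny_espec(k = 3, seed = 1)
  # an (effectively) frozen model: lr too small to move the weights,
  # so validation accuracy is constant from epoch 1 on
  fs <- finetune_spec(lr0 = 1e-300, plateau_patience = 3L, epochs = 6L,
                      k = 3, batch_size = 8, seed = 2)
  fit <- finetune(attach_classifier(build_encoder(es), 2), tr, va, fs)
  h <- fit$history
  expect_identical(length(unique(h$val_acc)), 1L)
  expect_identical(which(h$plateau), 4L)       # patience + 1
  expect_equal(h$lr[4], 1e-300 / 10)
  expect_equal(h$lr[1:3], rep(1e-300, 3))
})

test_that("a separable two-class fixture is learned quickly", {
  ds <- separable_dataset(n_subjects = 12, blocks = 4)
  d <- labeled_dataset(ds$clips)
  tr <- fmricontrast:::subset_subjects(d, sprintf("sub-%02d", 1:6))
  va <- fmricontrast:::subset_subjects(d, sprintf("sub-%02d", 7:8))
  te <- fmricontrast:::subset_subjects(d, sprintf("sub-%02d", 9:12))
  es <- desk_espec(k = 7, seed = 1)
  fs <- finetune_spec(lr0 = 3e-4, epochs = 20, k = 7, seed = 3,
                      init = "random", batch_size = 2)
  model <- attach_classifier(build_encoder(es), 2, init = "random", seed = 3)
  fit <- finetune(model, tr, va, fs)
  expect_gt(max(fit$history$val_acc), 0.9)
  # held-out prediction: planted pattern recovered for >= 90% of clips
  probs <- predict(fit$model, te)
  expect_identical(dim(probs), c(length(te$clips), 2L))
  expect_equal(rowSums(probs), rep(1, nrow(probs)), tolerance = 1e-6)
  pred <- d$classes[apply(probs, 1, which.max)]
  expect_gt(mean(pred == te$labels), 0.9)
  # deterministic repeat
  expect_identical(predict_clip(fit$model, te$clips[[1]]),
                   predict_clip(fit$model, te$clips[[1]]))
})

test_that("label shuffling drops accuracy to chance", {
  ds <- separable_dataset(n_subjects = 4, blocks = 3)
  d <- labeled_dataset(ds$clips)
  accs <- vapply(1:5, function(s) {
    shuffled <- d
    perm <- fmricontrast:::with_seed(1000 + s, sample(length(d$clips)))
    shuffled$clips <- lapply(seq_along(perm), function(i) {
      cl <- d$clips[[i]]
      cl$label <- d$labels[perm[i]]
      cl
    })
    shuffled <- labeled_dataset(shuffled$clips, classes = d$classes)
    tr <- fmricontrast:::subset_subjects(shuffled, sprintf("sub-%02d", 1:3))
    va <- fmricontrast:::subset_subjects(shuffled, "sub-04")
    es <- tiny_espec(k = 5, seed = s)
    fs <- finetune_spec(epochs = 4, k = 5, seed = s, init = "random")
    fit <- finetune(attach_classifier(build_encoder(es), 2, "random",
                                      seed = s), tr, va, fs)
    fit$history$val_acc[nrow(fit$history)]
  }, numeric(1))
  expect_gt(mean(accs), 0.35)
  expect_lt(mean(accs), 0.65)
})

test_that("dataset construction and split hygiene are enforced", {
  ds <- separable_dataset(n_subjects = 3, blocks = 2)
  d <- labeled_dataset(ds$clips)
  expect_identical(d$classes, c("faces", "houses"))
  unl <- ds$clips
  unl[[1]]$label <- NULL
  expect_error(labeled_dataset(unl), "label")
  expect_error(labeled_dataset(ds$clips, classes = "faces"), "outside|two")
  tr <- fmricontrast:::subset_subjects(d, c("sub-01", "sub-02"))
  va <- fmricontrast:::subset_subjects(d, c("sub-02", "sub-03"))
  es <- tiny_espec(k = 3)
  fs <- finetune_spec(epochs = 1, k = 3)
  expect_error(finetune(attach_classifier(build_encoder(es), 2), tr, va, fs),
               "overlap")
  sp <- fmricontrast:::inner_val_split(d, seed = 1)
  expect_length(intersect(unique(sp$train$subjects),
                          unique(sp$val$subjects)), 0)
  expect_identical(length(unique(sp$val$subjects)), 1L)
})
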