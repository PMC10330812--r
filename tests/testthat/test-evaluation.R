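test_that("subject folds partition subjects with near-equal sizes", {
  f <- subject_folds(sprintf("s%02d", 1:10), 5, seed = 1)
  expect_length(f, 5)
  expect_true(all(lengths(f) == 2))
  set.seed(20)
  for (n in sample(7:31, 8)) {
    subs <- sprintf("s%02d", seq_len(n))
    ff <- subject_folds(subs, 5, seed = n)
    expect_setequal(unlist(ff), subs)
    expect_identical(anyDuplicated(unlist(ff)), 0L)
    expect_lte(diff(range(lengths(ff))), 1)
  }
  expect_identical(subject_folds(sprintf("s%d", 1:9), 3, seed = 4),
                   subject_folds(sprintf("s%d", 1:9), 3, seed = 4))
  distinct <- vapply(1:5, function(s)
    !identical(subject_folds(sprintf("s%d", 1:20), 5, seed = s),
               subject_folds(sprintf("s%d", 1:20), 5, seed = s + 50)),
    logical(1))
  expect_true(any(distinct))
  expect_error(subject_folds(c("a", "b"), 5), "cannot fill")
})

test_that("confusion matrices count exactly", {
  perfect <- confusion(c("a", "a", "b"), c("a", "a", "b"), c("a", "b"))
  expect_identical(perfect, matrix(c(2L, 0L, 0L, 1L), 2,
                                   dimnames = list(true = c("a", "b"),
                                                   predicted = c("a", "b"))))
  onecol <- confusion(c("a", "b", "b"), c("a", "a", "a"), c("a", "b"))
  expect_identical(onecol[, "a"], c(a = 1L, b = 2L))
  expect_identical(sum(onecol[, "b"]), 0L)
  hand <- confusion(c("A", "A", "B", "B", "B"), c("A", "B", "B", "B", "A"),
                    c("A", "B"))
  expect_identical(matrix(hand, 2), matrix(c(1L, 1L, 1L, 2L), 2))
  expect_error(confusion("a", c("a", "b"), c("a", "b")), "length")
  expect_error(confusion("z", "a", c("a", "b")), "outside")
})

test_that("per-class F1 matches the formula including degenerate classes", {
  expect_equal(f1_per_class(diag(c(3L, 5L, 2L))), c(1, 1, 1),
               ignore_attr = TRUE)
  cm <- matrix(c(1L, 1L, 1L, 2L), 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(round(f1_per_class(cm), 3), c(A = 0.5, B = 0.667))
  # class never true nor predicted -> F1 = 0 by convention
  cm3 <- matrix(0L, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  cm3[1, 1] <- 4L; cm3[2, 2] <- 2L
  expect_identical(unname(f1_per_class(cm3)[3]), 0)
})

test_that("BH step-up agrees with hand cases and a brute-force oracle", {
  bh_oracle <- function(p, alpha) {
    m <- length(p)
    o <- order(p)
    passed <- which(p[o] <= seq_len(m) / m * alpha)
    rej <- logical(m)
    if (length(passed)) rej[o[seq_len(max(passed))]] <- TRUE
    rej
  }
  f1 <- matrix(rep(0.9, 12), 3)   # significant everywhere (variance 0)
  p1 <- c(0.001, 0.011, 0.02, 0.04)
  expect_identical(bh_oracle(p1, 0.05), rep(TRUE, 4))
  expect_identical(p.adjust(p1, "BH") < 0.05, rep(TRUE, 4))
  p2 <- c(0.01, 0.04, 0.04, 0.9)   # 0.04 > (2/4)*0.05: only the first passes
  expect_identical(bh_oracle(p2, 0.05), c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(p.adjust(p2, "BH") < 0.05, c(TRUE, FALSE, FALSE, FALSE))
  p3 <- c(0.01, 0.02, 0.03, 0.9)   # step-up rescues ranks 1-3, not 4
  expect_identical(bh_oracle(p3, 0.05), c(TRUE, TRUE, TRUE, FALSE))
  expect_identical(p.adjust(p3, "BH") < 0.05, c(TRUE, TRUE, TRUE, FALSE))
  set.seed(77)
  for (i in 1:300) {
    m <- sample(2:20, 1)
    p <- round(runif(m)^sample(1:3, 1), 4)
    expect_identical(p.adjust(p, "BH") <= 0.05, bh_oracle(p, 0.05))
  }
})

test_that("F1-vs-chance testing follows the one-sided t + BH recipe", {
  f1 <- cbind(a = c(0.8, 0.85, 0.8, 0.9), b = c(0.5, 0.52, 0.48, 0.5))
  res <- f1_vs_chance_test(f1, chance = 0.5)
  expect_identical(res$class, c("a", "b"))
  tt <- t.test(f1[, "a"], mu = 0.5, alternative = "greater")$p.value
  expect_equal(res$p[1], tt)
  expect_equal(res$p_adj, p.adjust(res$p, "BH"))
  expect_true(res$significant[1])
  expect_false(res$significant[2])
  # all folds exactly at chance: zero variance, p = 1, nothing significant
  flat <- matrix(0.5, 4, 3)
  expect_true(all(f1_vs_chance_test(flat, 0.5)$p == 1))
  # zero variance above chance: p = 0 by convention
  expect_true(all(f1_vs_chance_test(matrix(0.9, 4, 2), 0.5)$p == 0))
  expect_error(f1_vs_chance_test(matrix(0.5, 2, 2), 0.5), "folds")
})

test_that("permutation chance F1 tracks prevalence and predictor bias", {
  true <- rep(c("a", "b"), c(30, 10))
  pred <- rep("a", 40)                      # maximally biased predictor
  ch <- chance_f1(true, pred, c("a", "b"), B = 200, seed = 1)
  # permuting an all-"a" prediction always yields the same confusion
  expect_equal(unname(ch["a"]), 2 * 30 / (2 * 30 + 10), tolerance = 1e-12)
  expect_equal(unname(ch["b"]), 0)
  expect_identical(ch, chance_f1(true, pred, c("a", "b"), B = 200, seed = 1))
})

test_that("cross-validated evaluation is leak-free and learns the fixture", {
  # maximally separable fixture (very large amplitude, long rests) and a
  # pretrained initialisation: decoding should be nearly perfect
  sp <- sim_spec(n_subjects = 10, task_names = c("faces", "houses"),
                 blocks_per_run = 4, amplitude = 20, rest_duration_s = 20,
                 seed = 55)
  d <- labeled_dataset(generate_dataset(sp)$clips)
  enc <- acceptance_encoder(1L)
  fs <- finetune_spec(lr0 = 3e-4, epochs = 30, k = 7, init = "pretrained",
                      batch_size = 2, seed = 1)
  res <- run_cv(d, enc, fs, n_folds = 5, seed = 3, chance_B = 200)
  expect_s3_class(res, "cv_result")
  expect_identical(sum(res$confusion_pooled), length(d$clips))
  expect_equal(res$mean_acc, mean(res$fold_acc))
  # equal fold sizes here, so pooled accuracy equals the fold mean
  expect_equal(sum(diag(res$confusion_pooled)) / sum(res$confusion_pooled),
               mean(res$fold_acc), tolerance = 1e-9)
  expect_gt(res$mean_acc, 0.9)
  expect_true(all(res$per_fold_f1 >= 0 & res$per_fold_f1 <= 1))
  expect_true(all(res$f1_tests$significant))
})
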