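#' Partition subjects into cross-validation folds
#'
#' Subjects (not clips) are the unit of cross-validation, so no subject's
#' data can appear on both sides of a split. Fold sizes differ by at most
#' one.
#'
#' @param subject_ids Character vector (repetitions allowed; unique values
#'   are partitioned).
#' @param n_folds Number of folds (default 5).
#' @param seed Optional seed for the shuffle.
#' @return List of `n_folds` character vectors partitioning the subjects.
#' @export
subject_folds <- function(subject_ids, n_folds = 5L, seed = NULL) {
  subs <- unique(as.character(subject_ids))
  if (!is_count(n_folds) || n_folds < 2L) stop_fc("n_folds must be >= 2")
  if (length(subs) < n_folds)
    stop_fc(length(subs), " subject(s) cannot fill ", n_folds, " folds")
  perm <- with_seed(seed, sample(subs))
  split(perm, rep_len(seq_len(n_folds), length(perm)))
}

#' Confusion matrix
#'
#' @param true,pred Equal-length label vectors, both subsets of
#'   `class_order`.
#' @param class_order Class labels fixing the row/column order.
#' @return Square integer matrix; entry `(i, j)` counts items of true class
#'   `i` predicted as class `j`.
#' @export
confusion <- function(true, pred, class_order) {
  if (length(true) != length(pred))
    stop_fc("true and pred must have equal length")
  bad <- setdiff(unique(c(true, pred)), class_order)
  if (length(bad) > 0)
    stop_fc("labels outside class_order: ", paste(bad, collapse = ", "))
  ft <- factor(true, levels = class_order)
  fp <- factor(pred, levels = class_order)
  m <- table(true = ft, predicted = fp)
  matrix(as.integer(m), nrow = length(class_order),
         dimnames = list(true = class_order, predicted = class_order))
}

#' Per-class F1 scores from a confusion matrix
#'
#' `F1 = 2 TP / (2 TP + FP + FN)` per class; 0 by convention when the
#' denominator vanishes (class never true and never predicted).
#'
#' @param cm Square confusion matrix (rows true, columns predicted).
#' @return Named numeric vector of F1 scores in `[0, 1]`.
#' @export
f1_per_class <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm))
    stop_fc("cm must be a square matrix")
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  denom <- 2 * tp + fp + fn
  f1 <- ifelse(denom == 0, 0, 2 * tp / denom)
  names(f1) <- rownames(cm)
  f1
}

#' Permutation estimate of chance-level per-class F1
#'
#' Chance F1 depends on class prevalence and on the predictor's label
#' bias, so a flat `1/m` is generally wrong; this permutes the predicted
#' labels `B` times and averages the per-class F1, keeping both margins.
#'
#' @param true,pred Label vectors.
#' @param class_order Class labels.
#' @param B Number of permutations.
#' @param seed Optional seed.
#' @return Named numeric vector of chance F1 per class.
#' @export
chance_f1 <- function(true, pred, class_order, B = 1000L, seed = NULL) {
  with_seed(seed, {
    acc <- matrix(0, B, length(class_order))
    for (b in seq_len(B)) {
      acc[b, ] <- f1_per_class(confusion(true, sample(pred), class_order))
    }
    setNames(colMeans(acc), class_order)
  })
}

#' Test per-class F1 against chance with BH-FDR correction
#'
#' One-sided one-sample t-tests of the per-fold F1 scores against the
#' chance reference, per class, followed by Benjamini-Hochberg step-up
#' correction across classes at level `alpha`. Degenerate folds (zero
#' variance) give p = 0 when the common value beats chance and p = 1
#' otherwise.
#'
#' @param per_fold_f1 Matrix of F1 scores, folds in rows, classes in
#'   columns (>= 3 folds).
#' @param chance Per-class chance reference, e.g. from [chance_f1()], or a
#'   single number (recycled); `1/m` is an acceptable fallback.
#' @param alpha FDR level.
#' @return `data.frame` with `class`, `mean_f1`, `chance_f1`, `p`, `p_adj`,
#'   `significant`.
#' @export
f1_vs_chance_test <- function(per_fold_f1, chance, alpha = 0.05) {
  if (!is.matrix(per_fold_f1)) per_fold_f1 <- as.matrix(per_fold_f1)
  if (nrow(per_fold_f1) < 3L)
    stop_fc("need >= 3 folds for a t-test, got ", nrow(per_fold_f1))
  m <- ncol(per_fold_f1)
  chance <- rep_len(chance, m)
  p <- vapply(seq_len(m), function(j) {
    x <- per_fold_f1[, j]
    if (sd(x) < .Machine$double.eps^0.5) {
      return(if (mean(x) > chance[j]) 0 else 1)
    }
    t.test(x, mu = chance[j], alternative = "greater")$p.value
  }, numeric(1))
  p_adj <- p.adjust(p, method = "BH")
  classes <- colnames(per_fold_f1) %||% paste0("class", seq_len(m))
  data.frame(class = classes, mean_f1 = colMeans(per_fold_f1),
             chance_f1 = chance, p = p, p_adj = p_adj,
             significant = p_adj < alpha, row.names = NULL)
}

#' Subject-level cross-validated evaluation
#'
#' For each fold, fine-tunes a classifier (pretrained or random
#' initialisation) on the remaining folds -- with an inner subject-disjoint
#' validation split driving the plateau schedule -- then predicts centered
#' windows on the held-out subjects. Train and test subject sets are
#' verified disjoint on every fold.
#'
#' @param dataset A [labeled_dataset()].
#' @param encoder An `fmri_encoder` (pretrained checkpoint) used as
#'   initialisation; its spec also defines the random-init architecture.
#' @param fspec A [finetune_spec()]; `fspec$init` selects pretrained vs
#'   random initialisation.
#' @param n_folds Number of subject folds.
#' @param seed Seed for fold assignment and per-fold fine-tuning seeds.
#' @param alpha FDR level for the F1 significance tests.
#' @param chance_B Permutations for the chance-F1 reference.
#' @param verbose Print per-fold progress.
#' @return An object of class `cv_result`: per-fold accuracies (`fold_acc`),
#'   `mean_acc`, `sd_acc`, pooled and mean confusion matrices, per-fold
#'   per-class F1 matrix, and the [f1_vs_chance_test()] table.
#' @export
run_cv <- function(dataset, encoder, fspec, n_folds = 5L, seed = 1L,
                   alpha = 0.05, chance_B = 1000L, verbose = FALSE) {
  stopifnot(inherits(dataset, "fmri_dataset"),
            inherits(encoder, "fmri_encoder"),
            inherits(fspec, "finetune_spec"))
  folds <- subject_folds(dataset$subjects, n_folds,
                         seed = derive_seed(seed, 11L))
  classes <- dataset$classes
  fold_acc <- numeric(n_folds)
  per_fold_f1 <- matrix(NA_real_, n_folds, length(classes),
                        dimnames = list(NULL, classes))
  pooled <- matrix(0L, length(classes), length(classes),
                   dimnames = list(true = classes, predicted = classes))
  conf_sum <- matrix(0, length(classes), length(classes))
  all_true <- character(0)
  all_pred <- character(0)

  for (f in seq_len(n_folds)) {
    test_subs <- folds[[f]]
    train_subs <- setdiff(unique(dataset$subjects), test_subs)
    stopifnot(length(intersect(train_subs, test_subs)) == 0L)
    train_all <- subset_subjects(dataset, train_subs)
    test <- subset_subjects(dataset, test_subs)
    sp <- inner_val_split(train_all, seed = derive_seed(seed, 13L, f))

    fold_fspec <- fspec
    fold_fspec$seed <- derive_seed(seed, 17L, f)
    model <- attach_classifier(encoder, length(classes), init = fspec$init,
                               seed = fold_fspec$seed)
    fit <- finetune(model, sp$train, sp$val, fold_fspec)

    pred <- vapply(test$clips, function(cl) {
      p <- predict_clip(fit$model, cl, normalize = fspec$normalize)
      classes[which.max(p)]
    }, character(1))
    cm <- confusion(test$labels, pred, classes)
    fold_acc[f] <- sum(diag(cm)) / sum(cm)
    per_fold_f1[f, ] <- f1_per_class(cm)
    pooled <- pooled + cm
    conf_sum <- conf_sum + cm
    all_true <- c(all_true, test$labels)
    all_pred <- c(all_pred, pred)
    if (verbose)
      message(sprintf("fold %d/%d: accuracy %.3f", f, n_folds, fold_acc[f]))
  }

  ch <- chance_f1(all_true, all_pred, classes, B = chance_B,
                  seed = derive_seed(seed, 19L))
  sig <- f1_vs_chance_test(per_fold_f1, ch, alpha = alpha)
  structure(
    list(fold_acc = fold_acc, mean_acc = mean(fold_acc),
         sd_acc = sd(fold_acc), confusion_pooled = pooled,
         confusion_mean = conf_sum / n_folds, per_fold_f1 = per_fold_f1,
         f1_tests = sig, n_clips = sum(pooled), classes = classes),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds, accuracy %.3f +/- %.3f (%d clips)\n",
              length(x$fold_acc), x$mean_acc, x$sd_acc, x$n_clips))
  cat("per-class F1 (mean over folds):\n")
  print(round(colMeans(x$per_fold_f1), 3))
  sig <- x$f1_tests$class[x$f1_tests$significant]
  cat("above chance (BH-corrected):",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  invisible(x)
}
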