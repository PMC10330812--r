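#' Fine-tuning hyperparameters
#'
#' Cross-entropy fine-tuning with Adam; the learning rate is divided by
#' `plateau_factor` whenever the best validation accuracy has not improved
#' for `plateau_patience` consecutive epochs (best-so-far comparison at
#' tolerance 0). A budget of 30 epochs suits same-source transfer, 60 the
#' slower cross-source case.
#'
#' @param lr0 Initial learning rate.
#' @param plateau_factor Divide-by factor on plateau (> 1).
#' @param plateau_patience Epochs without improvement triggering a drop.
#' @param epochs Epoch budget.
#' @param k Input window frames; must equal the encoder's `k`.
#' @param init `"pretrained"` (reuse checkpoint weights) or `"random"`
#'   (re-draw the encoder).
#' @param batch_size Windows per optimisation step.
#' @param normalize Per-clip normalisation before the window is cut:
#'   `"voxel"` (default), `"global"` or `"none"` (must match pretraining).
#' @param seed Seed for shuffles, window offsets and (random init) weights.
#' @return An object of class `finetune_spec`.
#' @export
finetune_spec <- function(lr0 = 1e-4, plateau_factor = 10, plateau_patience = 10L,
                          epochs = 30L, k, init = c("pretrained", "random"),
                          batch_size = 16L, normalize = "voxel", seed = 1L) {
  init <- match.arg(init)
  if (!is_count(epochs) || epochs < 1) stop_fc("epochs must be >= 1")
  if (plateau_factor <= 1) stop_fc("plateau_factor must be > 1")
  if (!is_count(plateau_patience) || plateau_patience < 1)
    stop_fc("plateau_patience must be >= 1")
  if (!is_count(k) || k < 1) stop_fc("k must be a positive integer")
  normalizer(normalize)   # validates
  normalize <- if (isTRUE(normalize)) "voxel"
               else if (identical(normalize, FALSE)) "none" else normalize
  structure(list(lr0 = lr0, plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 epochs = as.integer(epochs), k = as.integer(k), init = init,
                 batch_size = as.integer(batch_size),
                 normalize = normalize, seed = as.integer(seed)),
            class = "finetune_spec")
}

#' Bundle labelled clips into a dataset
#'
#' @param clips List of `fmri_clip` objects, each carrying a `label`.
#' @param classes Optional class order; defaults to the sorted unique
#'   labels. At least two classes are required.
#' @return An object of class `fmri_dataset` with fields `clips`, `classes`,
#'   `subjects`, `labels`.
#' @export
labeled_dataset <- function(clips, classes = NULL) {
  if (length(clips) == 0L) stop_fc("no clips supplied")
  labels <- vapply(clips, function(cl) cl$label %||% NA_character_,
                   character(1))
  if (anyNA(labels)) stop_fc("every clip must carry a condition label")
  if (is.null(classes)) classes <- sort(unique(labels))
  if (!all(labels %in% classes))
    stop_fc("labels outside the class list: ",
            paste(setdiff(labels, classes), collapse = ", "))
  if (length(classes) < 2L) stop_fc("at least two classes are required")
  subjects <- vapply(clips, function(cl) cl$subject_id, character(1))
  structure(list(clips = clips, classes = classes, subjects = subjects,
                 labels = labels),
            class = "fmri_dataset")
}

#' @export
print.fmri_dataset <- function(x, ...) {
  cat(sprintf("<fmri_dataset> %d clips, %d subjects, classes: %s\n",
              length(x$clips), length(unique(x$subjects)),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

# Restrict a dataset to a subject subset.
subset_subjects <- function(dataset, subjects) {
  keep <- dataset$subjects %in% subjects
  labeled_dataset(dataset$clips[keep], classes = dataset$classes)
}

#' Cut a k-frame window out of a clip
#'
#' Training uses a uniformly random valid offset; evaluation uses the
#' centered window.
#'
#' @param clip An `fmri_clip` with at least `k` frames.
#' @param k Window length in frames.
#' @param mode `"random"` or `"centered"`.
#' @param seed Optional seed for the random offset.
#' @return 4-D array of `k` frames.
#' @export
sample_window <- function(clip, k, mode = c("random", "centered"),
                          seed = NULL) {
  mode <- match.arg(mode)
  nt <- n_frames(clip)
  if (!is_count(k) || k < 1) stop_fc("k must be a positive integer")
  if (nt < k)
    stop_fc("clip has ", nt, " frames, shorter than the window k = ", k)
  off <- if (mode == "centered") (nt - k) %/% 2L
         else with_seed(seed, sample.int(nt - k + 1L, 1L) - 1L)
  clip$data[(off + 1L):(off + k), , , , drop = FALSE]
}

#' Attach a linear classifier head to an encoder
#'
#' The projection head is dropped and a single fully connected layer
#' `feature_dim -> n_classes` is appended. With `init = "pretrained"` the
#' encoder weights are copied from `encoder`; with `"random"` they are
#' re-drawn. The classifier layer itself is initialised deterministically
#' from `seed`, so attaching twice to one checkpoint yields identical
#' initial logits.
#'
#' @param encoder An `fmri_encoder` (e.g. from [load_checkpoint()]).
#' @param n_classes Number of target classes (>= 2).
#' @param init `"pretrained"` or `"random"`.
#' @param seed Seed for the new weights; defaults to the encoder spec seed.
#' @return An object of class `fmri_classifier`.
#' @export
attach_classifier <- function(encoder, n_classes,
                              init = c("pretrained", "random"), seed = NULL) {
  stopifnot(inherits(encoder, "fmri_encoder"))
  init <- match.arg(init)
  if (!is_count(n_classes) || n_classes < 2L)
    stop_fc("n_classes must be an integer >= 2")
  spec <- encoder$spec
  seed <- seed %||% spec$seed
  if (init == "random") {
    rspec <- spec
    rspec$seed <- as.integer(seed)
    params <- init_params(rspec, n_classes = n_classes)
  } else {
    params <- encoder$params
    cls <- with_seed(derive_seed(seed, 7L),
                     list(W = he_weights(n_classes, spec$feature_dim),
                          b = numeric(n_classes)))
    params[["cls.W"]] <- cls$W
    params[["cls.b"]] <- cls$b
  }
  # the projection head plays no role in classification
  params[["h1.W"]] <- NULL; params[["h1.b"]] <- NULL
  params[["h2.W"]] <- NULL; params[["h2.b"]] <- NULL
  structure(list(spec = spec, params = params,
                 n_classes = as.integer(n_classes), classes = NULL),
            class = "fmri_classifier")
}

#' @export
print.fmri_classifier <- function(x, ...) {
  cat(sprintf("<fmri_classifier> k = %d, feature %d -> %d classes%s\n",
              x$spec$k, x$spec$feature_dim, x$n_classes,
              if (is.null(x$classes)) ""
              else paste0(" (", paste(x$classes, collapse = ", "), ")")))
  invisible(x)
}

# Normalise the whole clip (temporal statistics need all frames), then cut
# the k-frame window.
classifier_window <- function(clip, fspec, mode) {
  nfun <- normalizer(fspec$normalize)
  if (!is.null(nfun)) clip$data <- nfun(clip$data)
  sample_window(clip, fspec$k, mode)
}

dataset_accuracy <- function(model, dataset, fspec) {
  pred <- vapply(dataset$clips, function(cl) {
    p <- encoder_forward(model$params, model$spec,
                         classifier_window(cl, fspec, "centered"),
                         "classifier")$out
    dataset$classes[which.max(p)]
  }, character(1))
  mean(pred == dataset$labels)
}

#' Fine-tune a classifier on labelled clips
#'
#' Minimises the cross-entropy of the linear head (and the whole encoder,
#' end-to-end) by Adam on randomly placed `k`-frame windows. Validation
#' accuracy on centered windows is logged per epoch and drives the plateau
#' schedule; the weights of the best validation epoch are returned.
#'
#' @param model An `fmri_classifier` from [attach_classifier()].
#' @param train,val [labeled_dataset()]s; `val` must be subject-disjoint
#'   from `train`.
#' @param fspec A [finetune_spec()].
#' @param verbose Print one line per epoch.
#' @return List with `model` (best-epoch `fmri_classifier`, with `classes`
#'   filled in) and `history` (`data.frame` with `epoch`, `train_loss`,
#'   `val_acc`, `lr`, `plateau`).
#' @export
finetune <- function(model, train, val, fspec, verbose = FALSE) {
  stopifnot(inherits(model, "fmri_classifier"),
            inherits(train, "fmri_dataset"), inherits(val, "fmri_dataset"),
            inherits(fspec, "finetune_spec"))
  if (!identical(train$classes, val$classes))
    stop_fc("train and val must share one class list")
  if (length(intersect(unique(train$subjects), unique(val$subjects))) > 0)
    stop_fc("validation subjects overlap training subjects")
  if (length(train$classes) != model$n_classes)
    stop_fc("model has ", model$n_classes, " outputs but the data ",
            length(train$classes), " classes")
  if (fspec$k != model$spec$k)
    stop_fc("fspec k (", fspec$k, ") must equal the encoder k (",
            model$spec$k, ")")
  if (any(vapply(train$clips, n_frames, integer(1)) < fspec$k))
    stop_fc("training clip(s) shorter than k = ", fspec$k)

  params <- model$params
  spec <- model$spec
  opt <- adam_state(params)
  lr <- fspec$lr0
  best <- list(acc = -Inf, params = params, epoch = 0L)
  since_improve <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_acc = numeric(0), lr = numeric(0),
                        plateau = logical(0))
  y_index <- match(train$labels, train$classes)

  with_seed(fspec$seed, {
    for (e in seq_len(fspec$epochs)) {
      batches <- epoch_batches(length(train$clips), fspec$batch_size)
      losses <- numeric(0)
      for (ix in batches) {
        gacc <- NULL
        bl <- numeric(length(ix))
        for (j in seq_along(ix)) {
          i <- ix[j]
          w <- classifier_window(train$clips[[i]], fspec, "random")
          fw <- encoder_forward(params, spec, w, "classifier",
                                want_cache = TRUE)
          p <- softmax(fw$out)
          bl[j] <- -log(max(p[y_index[i]], 1e-12))
          dlogits <- p
          dlogits[y_index[i]] <- dlogits[y_index[i]] - 1
          gacc <- acc_grads(gacc, encoder_backward(params, spec, fw$cache,
                                                   dlogits))
        }
        if (!all(is.finite(bl)))
          stop_fc("fine-tuning diverged at epoch ", e, ": non-finite loss")
        gacc <- scale_grads(gacc, 1 / length(ix))
        st <- adam_step(params, gacc, opt, lr)
        params <- st$params
        opt <- st$state
        losses <- c(losses, bl)
      }
      model$params <- params
      acc <- dataset_accuracy(model, val, fspec)
      plateau <- FALSE
      if (acc > best$acc) {
        best <- list(acc = acc, params = params, epoch = e)
        since_improve <- 0L
      } else {
        since_improve <- since_improve + 1L
        if (since_improve >= fspec$plateau_patience) {
          lr <- lr / fspec$plateau_factor
          since_improve <- 0L
          plateau <- TRUE
        }
      }
      history[e, ] <- list(e, mean(losses), acc, lr, plateau)
      if (verbose)
        message(sprintf("epoch %d, train_loss %.4f, val_acc %.3f, lr %.2e",
                        e, mean(losses), acc, lr))
    }
  })
  model$params <- best$params
  model$classes <- train$classes
  attr(model, "best_epoch") <- best$epoch
  list(model = model, history = history)
}

#' Class probabilities for a clip
#'
#' Evaluates the classifier on the centered `k`-frame window of a clip.
#'
#' @param model A fitted `fmri_classifier`.
#' @param clip An `fmri_clip` with at least `k` frames.
#' @param normalize Per-clip normalisation (must match training).
#' @return Named probability vector summing to 1.
#' @export
predict_clip <- function(model, clip, normalize = "voxel") {
  stopifnot(inherits(model, "fmri_classifier"))
  nfun <- normalizer(normalize)
  if (!is.null(nfun)) clip$data <- nfun(clip$data)
  w <- sample_window(clip, model$spec$k, "centered")
  p <- softmax(encoder_forward(model$params, model$spec, w, "classifier")$out)
  names(p) <- model$classes %||% paste0("class", seq_along(p))
  p
}

#' @export
predict.fmri_classifier <- function(object, newdata, ...) {
  if (inherits(newdata, "fmri_clip")) return(predict_clip(object, newdata))
  stopifnot(inherits(newdata, "fmri_dataset"))
  t(vapply(newdata$clips, function(cl) predict_clip(object, cl),
           numeric(object$n_classes)))
}

# In-training validation split: hold out one subject, or 10% of the
# training subjects, whichever is larger.
inner_val_split <- function(dataset, seed = NULL) {
  subs <- unique(dataset$subjects)
  if (length(subs) < 2L)
    stop_fc("need >= 2 subjects to carve out a validation subject")
  n_val <- max(1L, ceiling(0.1 * length(subs)))
  val_subs <- with_seed(seed, sample(subs, n_val))
  list(train = subset_subjects(dataset, setdiff(subs, val_subs)),
       val = subset_subjects(dataset, val_subs))
}
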