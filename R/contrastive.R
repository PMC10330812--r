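#' Cosine similarity
#'
#' `sim(x, y) = (x . y) / (||x||_2 ||y||_2)`, clipped to `[-1, 1]` against
#' roundoff.
#'
#' @param x,y Nonzero numeric vectors of equal length.
#' @return Scalar in `[-1, 1]`.
#' @export
cosine_sim <- function(x, y) {
  if (length(x) != length(y))
    stop_fc("vectors have different lengths (", length(x), " vs ",
            length(y), ")")
  nx <- sqrt(sum(x * x))
  ny <- sqrt(sum(y * y))
  if (nx == 0 || ny == 0)
    stop_fc("cosine similarity is undefined for a zero vector")
  min(1, max(-1, sum(x * y) / (nx * ny)))
}

#' Temporal-contrastive triplet loss
#'
#' A two-term softmax cross-entropy over cosine similarities of segment
#' embeddings: `loss = -log( exp(s_pos) / (exp(s_pos) + exp(s_neg)) )`.
#' By default (`pair_order = "text"`) the positive pair is middle-end,
#' `s_pos = sim(y2, y3)`, and the negative pair beginning-end,
#' `s_neg = sim(y1, y3)` -- temporally adjacent segments are pulled
#' together, distant ones pushed apart. `pair_order = "printed"` swaps the
#' roles (numerator `sim(y1, y3)`), matching the literal index order some
#' write-ups print for this loss; it is provided for comparison only.
#'
#' Since both similarities lie in `[-1, 1]` the loss is bounded inside
#' `[log(1 + exp(-2)), log(1 + exp(2))]`.
#'
#' @param y1,y2,y3 Embeddings of the beginning, middle and end segments.
#' @param pair_order `"text"` (default) or `"printed"`, see Details.
#' @return Nonnegative scalar loss.
#' @export
triplet_loss <- function(y1, y2, y3, pair_order = c("text", "printed")) {
  pair_order <- match.arg(pair_order)
  s_me <- cosine_sim(y2, y3)
  s_be <- cosine_sim(y1, y3)
  if (pair_order == "text") log1p(exp(s_be - s_me)) else log1p(exp(s_me - s_be))
}

#' Mean triplet loss over a batch of embedding triplets
#'
#' @param triplets Nonempty list; each element a list/embedding triplet with
#'   components `y1`, `y2`, `y3`.
#' @param pair_order Passed to [triplet_loss()].
#' @return Scalar mean loss.
#' @export
batch_loss <- function(triplets, pair_order = c("text", "printed")) {
  pair_order <- match.arg(pair_order)
  if (length(triplets) == 0L) stop_fc("batch of embedding triplets is empty")
  mean(vapply(triplets,
              function(tr) triplet_loss(tr$y1, tr$y2, tr$y3, pair_order),
              numeric(1)))
}

# Gradient of cosine_sim(x, y) with respect to x.
dcos_dx <- function(x, y, s) {
  nx <- sqrt(sum(x * x)); ny <- sqrt(sum(y * y))
  y / (nx * ny) - s * x / (nx * nx)
}

# Loss value and gradients w.r.t. the three embeddings.
triplet_loss_grad <- function(y1, y2, y3, pair_order = "text") {
  s_me <- cosine_sim(y2, y3)
  s_be <- cosine_sim(y1, y3)
  d <- if (pair_order == "text") s_be - s_me else s_me - s_be
  loss <- log1p(exp(d))
  sig <- 1 / (1 + exp(-d))          # dloss/dd
  sgn <- if (pair_order == "text") 1 else -1
  # d = sgn * (s_be - s_me)
  d_sbe <- sig * sgn
  d_sme <- -sig * sgn
  list(loss = loss,
       dy1 = d_sbe * dcos_dx(y1, y3, s_be),
       dy2 = d_sme * dcos_dx(y2, y3, s_me),
       dy3 = d_sbe * dcos_dx(y3, y1, s_be) + d_sme * dcos_dx(y3, y2, s_me))
}

#' Optimisation hyperparameters for pretraining
#'
#' Adam with an exponentially decayed learning rate:
#' `lr(epoch) = lr0 * lr_decay_per_epoch^epoch` (epoch counted 0-based, so
#' the first epoch runs at `lr0`).
#'
#' @param lr0 Initial learning rate.
#' @param lr_decay_per_epoch Multiplicative decay per epoch, in (0, 1].
#' @param batch_size Triplets per optimisation step.
#' @param epochs Pretraining epochs.
#' @param adam_beta1,adam_beta2 Adam moment decay rates.
#' @param seed Seed controlling initialisation-independent randomness
#'   (shuffles, segment placement).
#' @return An object of class `train_spec`.
#' @export
train_spec <- function(lr0 = 1e-4, lr_decay_per_epoch = 0.99,
                       batch_size = 16L, epochs = 100L, adam_beta1 = 0.9,
                       adam_beta2 = 0.999, seed = 1L) {
  if (lr0 <= 0) stop_fc("lr0 must be positive")
  if (lr_decay_per_epoch <= 0 || lr_decay_per_epoch > 1)
    stop_fc("lr_decay_per_epoch must lie in (0, 1]")
  if (!is_count(epochs) || epochs < 1) stop_fc("epochs must be >= 1")
  if (!is_count(batch_size) || batch_size < 1)
    stop_fc("batch_size must be >= 1")
  structure(list(lr0 = lr0, lr_decay_per_epoch = lr_decay_per_epoch,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, seed = as.integer(seed)),
            class = "train_spec")
}

#' Learning rate after a number of completed epochs
#'
#' @param tspec A [train_spec()].
#' @param epoch Number of completed epochs (0 gives `lr0`).
#' @return Learning rate.
#' @export
lr_at <- function(tspec, epoch) {
  tspec$lr0 * tspec$lr_decay_per_epoch^epoch
}

#' Self-supervised pretraining on unlabeled clips
#'
#' Each epoch visits every clip once in a seeded shuffle, draws a fresh
#' (beginning, middle, end) triplet per clip, embeds the three segments with
#' the projection head, and minimises the mean [triplet_loss()] by Adam.
#' The whole run -- initialisation, shuffles, segment placements -- is a
#' pure function of `espec$seed` and `tspec$seed`.
#'
#' @param clips List of `fmri_clip` objects, all long enough for `pcfg`.
#' @param pcfg A [pretext_config()].
#' @param espec An [encoder_spec()] with `k == pcfg$k`.
#' @param tspec A [train_spec()].
#' @param pair_order Passed to the loss; `"text"` keeps middle-end positive.
#' @param checkpoint_path If non-`NULL`, a checkpoint is written here every
#'   `checkpoint_every` epochs and at the end.
#' @param checkpoint_every Epoch interval for checkpoints.
#' @param verbose Print one line per epoch (`epoch, mean_loss, lr`).
#' @return List with elements `encoder` (trained `fmri_encoder`) and
#'   `history` (`data.frame` with `epoch`, `mean_loss`, `lr`, `seconds`).
#' @export
pretrain <- function(clips, pcfg, espec, tspec, pair_order = "text",
                     checkpoint_path = NULL, checkpoint_every = 10L,
                     verbose = FALSE) {
  stopifnot(inherits(pcfg, "pretext_config"), inherits(espec, "encoder_spec"),
            inherits(tspec, "train_spec"))
  if (espec$k != pcfg$k)
    stop_fc("encoder k (", espec$k, ") must equal pretext k (", pcfg$k, ")")
  need <- min_clip_frames(pcfg)
  lens <- vapply(clips, n_frames, integer(1))
  if (any(lens < need))
    stop_fc(sum(lens < need), " clip(s) are shorter than the required ",
            need, " frames")

  encoder <- build_encoder(espec)
  params <- encoder$params
  opt <- adam_state(params)
  history <- data.frame(epoch = integer(0), mean_loss = numeric(0),
                        lr = numeric(0), seconds = numeric(0))

  with_seed(tspec$seed, {
    for (e in seq_len(tspec$epochs)) {
      t0 <- proc.time()[["elapsed"]]
      lr <- lr_at(tspec, e - 1L)
      batches <- epoch_batches(length(clips), tspec$batch_size)
      epoch_losses <- numeric(0)
      for (ix in batches) {
        gacc <- NULL
        bloss <- numeric(length(ix))
        for (j in seq_along(ix)) {
          tri <- make_triplet(clips[[ix[j]]], pcfg)
          f1 <- encoder_forward(params, espec, tri$beginning, "projection",
                                want_cache = TRUE)
          f2 <- encoder_forward(params, espec, tri$middle, "projection",
                                want_cache = TRUE)
          f3 <- encoder_forward(params, espec, tri$end, "projection",
                                want_cache = TRUE)
          lg <- triplet_loss_grad(f1$out, f2$out, f3$out, pair_order)
          if (!is.finite(lg$loss))
            stop_fc("pretraining diverged at epoch ", e,
                    ": non-finite loss; lower lr0 or check the inputs")
          bloss[j] <- lg$loss
          gacc <- acc_grads(gacc, encoder_backward(params, espec, f1$cache,
                                                   lg$dy1))
          gacc <- acc_grads(gacc, encoder_backward(params, espec, f2$cache,
                                                   lg$dy2))
          gacc <- acc_grads(gacc, encoder_backward(params, espec, f3$cache,
                                                   lg$dy3))
        }
        gacc <- scale_grads(gacc, 1 / length(ix))
        st <- adam_step(params, gacc, opt, lr, tspec$adam_beta1,
                        tspec$adam_beta2)
        params <- st$params
        opt <- st$state
        epoch_losses <- c(epoch_losses, bloss)
      }
      history[e, ] <- list(e, mean(epoch_losses), lr,
                           proc.time()[["elapsed"]] - t0)
      if (verbose)
        message(sprintf("epoch %d, mean_loss %.5f, lr %.3e", e,
                        mean(epoch_losses), lr))
      if (!is.null(checkpoint_path) && checkpoint_every > 0 &&
          (e %% checkpoint_every == 0L || e == tspec$epochs)) {
        encoder$params <- params
        save_checkpoint(encoder, checkpoint_path, history)
      }
    }
  })
  encoder$params <- params
  list(encoder = encoder, history = history)
}
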