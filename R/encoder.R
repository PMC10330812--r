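#' Architecture specification of the volumetric encoder
#'
#' The encoder is a temporal convolution followed by four 3-D residual
#' stages and a head. The temporal layer is a convolution whose kernel spans
#' all `k` input frames at each 3x3x3 spatial neighbourhood, collapsing time
#' into `base_channels` 3-D feature maps. Each residual stage holds two
#' blocks of two 3x3x3 convolutions with instance normalisation, ReLU and an
#' identity shortcut; stages 2-4 enter with stride-2 spatial downsampling
#' and a projected (1x1x1) shortcut. Global spatial average pooling yields a
#' `feature_dim`-vector (`feature_dim` equals the last stage's width), and
#' the projection head (linear - ReLU - linear) maps it to contrast space.
#'
#' @param k Input frames per segment.
#' @param base_channels Channels produced by the temporal layer.
#' @param stage_channels Widths of the four residual stages.
#' @param proj_hidden Hidden width of the projection head.
#' @param contrast_dim Output width in contrast space.
#' @param stem_stride Spatial stride of the temporal stem convolution (1 or
#'   2). The default 2 mirrors the strided stem of residual image networks
#'   and quarters the cost of the first stage.
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `encoder_spec`.
#' @export
encoder_spec <- function(k, base_channels = 16L,
                         stage_channels = c(16L, 32L, 64L, 128L),
                         proj_hidden = 128L, contrast_dim = 64L,
                         stem_stride = 2L, seed = 1L) {
  if (!is_count(k) || k < 1) stop_fc("k must be a positive integer")
  if (length(stage_channels) != 4L)
    stop_fc("exactly four residual stages are required")
  widths <- c(base_channels, stage_channels, proj_hidden, contrast_dim)
  if (any(!vapply(widths, is_count, logical(1))) || any(widths < 1))
    stop_fc("all widths must be positive integers")
  if (!stem_stride %in% c(1L, 2L)) stop_fc("stem_stride must be 1 or 2")
  structure(
    list(k = as.integer(k), base_channels = as.integer(base_channels),
         stage_channels = as.integer(stage_channels),
         feature_dim = as.integer(stage_channels[4]),
         proj_hidden = as.integer(proj_hidden),
         contrast_dim = as.integer(contrast_dim),
         stem_stride = as.integer(stem_stride), seed = as.integer(seed)),
    class = "encoder_spec"
  )
}

# One row per residual block: input/output channels, stride, projection?
# Memoised: the layout is pure in the channel widths and this sits in the
# training hot path.
.layout_cache <- new.env(parent = emptyenv())

encoder_layout <- function(spec) {
  key <- paste(spec$base_channels, paste(spec$stage_channels, collapse = ","))
  hit <- .layout_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- list()
  inch <- spec$base_channels
  for (s in 1:4) {
    width <- spec$stage_channels[s]
    for (b in 1:2) {
      stride <- if (b == 1L && s > 1L) 2L else 1L
      name <- sprintf("s%db%d", s, b)
      leaf <- c("c1W", "c1b", "n1g", "n1b", "c2W", "c2b", "n2g", "n2b",
                "pW", "pb", "pg", "pnb")
      out[[length(out) + 1L]] <- list(
        name = name, inch = inch, outch = width, stride = stride,
        proj = (b == 1L) && (stride != 1L || inch != width),
        nm = setNames(as.list(paste0(name, ".", leaf)), leaf))
      inch <- width
    }
  }
  .layout_cache[[key]] <- out
  out
}

init_params <- function(spec, n_classes = NULL) {
  with_seed(spec$seed, {
    p <- list()
    k3 <- 27L
    p[["t.W"]] <- he_weights(spec$base_channels, spec$k * k3)
    p[["t.b"]] <- numeric(spec$base_channels)
    p[["t.g"]] <- rep(1, spec$base_channels)
    p[["t.be"]] <- numeric(spec$base_channels)
    for (blk in encoder_layout(spec)) {
      nm <- blk$name
      p[[paste0(nm, ".c1W")]] <- he_weights(blk$outch, blk$inch * k3)
      p[[paste0(nm, ".c1b")]] <- numeric(blk$outch)
      p[[paste0(nm, ".n1g")]] <- rep(1, blk$outch)
      p[[paste0(nm, ".n1b")]] <- numeric(blk$outch)
      p[[paste0(nm, ".c2W")]] <- he_weights(blk$outch, blk$outch * k3)
      p[[paste0(nm, ".c2b")]] <- numeric(blk$outch)
      p[[paste0(nm, ".n2g")]] <- rep(1, blk$outch)
      p[[paste0(nm, ".n2b")]] <- numeric(blk$outch)
      if (blk$proj) {
        p[[paste0(nm, ".pW")]] <- he_weights(blk$outch, blk$inch)
        p[[paste0(nm, ".pb")]] <- numeric(blk$outch)
        p[[paste0(nm, ".pg")]] <- rep(1, blk$outch)
        p[[paste0(nm, ".pnb")]] <- numeric(blk$outch)
      }
    }
    # head biases carry a little noise so an all-dead ReLU hidden layer
    # cannot produce an exactly-zero embedding (cosine is undefined there)
    p[["h1.W"]] <- he_weights(spec$proj_hidden, spec$feature_dim)
    p[["h1.b"]] <- rnorm(spec$proj_hidden, sd = 0.01)
    p[["h2.W"]] <- he_weights(spec$contrast_dim, spec$proj_hidden)
    p[["h2.b"]] <- rnorm(spec$contrast_dim, sd = 0.01)
    if (!is.null(n_classes)) {
      p[["cls.W"]] <- he_weights(n_classes, spec$feature_dim)
      p[["cls.b"]] <- numeric(n_classes)
    }
    p
  })
}

#' Build an encoder from a specification
#'
#' Weights are drawn deterministically from `spec$seed`: two encoders built
#' from the same spec are identical.
#'
#' @param spec An [encoder_spec()].
#' @return An object of class `fmri_encoder`.
#' @export
build_encoder <- function(spec) {
  stopifnot(inherits(spec, "encoder_spec"))
  structure(list(spec = spec, params = init_params(spec)),
            class = "fmri_encoder")
}

#' @export
print.fmri_encoder <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    paste0("<fmri_encoder> k = %d, channels %d | %s, feature %d, ",
           "contrast %d (%s parameters)\n"),
    s$k, s$base_channels, paste(s$stage_channels, collapse = "-"),
    s$feature_dim, s$contrast_dim,
    format(count_params(x), big.mark = ",")))
  invisible(x)
}

#' Total number of trainable parameters
#' @param encoder An `fmri_encoder` or `fmri_classifier`.
#' @return Integer parameter count.
#' @export
count_params <- function(encoder) {
  sum(vapply(encoder$params, length, integer(1)))
}

MIN_SPATIAL <- 8L

check_segment <- function(spec, x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 4L)
    stop_fc("segment must be a 4-D (frames, x, y, z) array")
  if (d[1] != spec$k)
    stop_fc("segment has ", d[1], " frames but the encoder expects k = ",
            spec$k)
  if (any(d[2:4] < MIN_SPATIAL))
    stop_fc("spatial extent ", paste(d[2:4], collapse = "x"),
            " is below the encoder's minimum of ", MIN_SPATIAL,
            " voxels per axis")
  invisible(TRUE)
}

block_fw <- function(x, p, blk) {
  nm <- blk$nm
  c1 <- conv_fw(x, p[[nm$c1W]], p[[nm$c1b]], 3L, blk$stride)
  n1 <- inorm_fw(c1, p[[nm$n1g]], p[[nm$n1b]])
  r1 <- relu_fw(n1$y)
  c2 <- conv_fw(r1, p[[nm$c2W]], p[[nm$c2b]], 3L, 1L)
  n2 <- inorm_fw(c2, p[[nm$n2g]], p[[nm$n2b]])
  if (blk$proj) {
    cp <- conv_fw(x, p[[nm$pW]], p[[nm$pb]], 1L, blk$stride, 0L)
    np <- inorm_fw(cp, p[[nm$pg]], p[[nm$pnb]])
    sc <- np$y
  } else {
    np <- NULL
    sc <- x
  }
  y <- relu_fw(n2$y + sc)
  list(y = y, x = x, n1 = n1, r1 = r1, n2 = n2, np = np)
}

block_bw <- function(cache, p, blk, dy) {
  nm <- blk$nm
  g <- list()
  dsum <- relu_bw(cache$y, dy)
  bn2 <- inorm_bw(cache$n2, p[[nm$n2g]], dsum)
  g[[nm$n2g]] <- bn2$dgamma
  g[[nm$n2b]] <- bn2$dbeta
  bc2 <- conv_bw(cache$r1, p[[nm$c2W]], bn2$dx, 3L, 1L)
  g[[nm$c2W]] <- bc2$dW
  g[[nm$c2b]] <- bc2$db
  dr1 <- relu_bw(cache$r1, bc2$dx)
  bn1 <- inorm_bw(cache$n1, p[[nm$n1g]], dr1)
  g[[nm$n1g]] <- bn1$dgamma
  g[[nm$n1b]] <- bn1$dbeta
  bc1 <- conv_bw(cache$x, p[[nm$c1W]], bn1$dx, 3L, blk$stride)
  g[[nm$c1W]] <- bc1$dW
  g[[nm$c1b]] <- bc1$db
  dx <- bc1$dx
  if (blk$proj) {
    bnp <- inorm_bw(cache$np, p[[nm$pg]], dsum)
    g[[nm$pg]] <- bnp$dgamma
    g[[nm$pnb]] <- bnp$dbeta
    bcp <- conv_bw(cache$x, p[[nm$pW]], bnp$dx, 1L, blk$stride, 0L)
    g[[nm$pW]] <- bcp$dW
    g[[nm$pb]] <- bcp$db
    dx <- dx + bcp$dx
  } else {
    dx <- dx + dsum
  }
  list(dx = dx, grads = g)
}

# Full forward pass; head is "projection", "feature" or "classifier"
# (classifier requires cls.* params). Returns the output vector and, when
# want_cache, everything the backward pass needs.
encoder_forward <- function(params, spec, x, head = "projection",
                            want_cache = FALSE) {
  check_segment(spec, x)
  ct <- conv_fw(x, params[["t.W"]], params[["t.b"]], 3L, spec$stem_stride)
  nt <- inorm_fw(ct, params[["t.g"]], params[["t.be"]])
  rt <- relu_fw(nt$y)
  h <- rt
  blocks <- encoder_layout(spec)
  bcaches <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    bc <- block_fw(h, params, blocks[[i]])
    if (want_cache) bcaches[[i]] <- bc
    h <- bc$y
  }
  pdims <- dim(h)
  ln <- lnorm_fw(pool_fw(h))   # layer-normalised pooled feature
  feat <- ln$y
  hr1 <- NULL
  out <- switch(head,
    feature = feat,
    projection = {
      hr1 <- relu_fw(dense_fw(feat, params[["h1.W"]], params[["h1.b"]]))
      dense_fw(hr1, params[["h2.W"]], params[["h2.b"]])
    },
    classifier = dense_fw(feat, params[["cls.W"]], params[["cls.b"]]),
    stop_fc("unknown head: ", head)
  )
  if (!want_cache) return(list(out = out))
  list(out = out,
       cache = list(x = x, nt = nt, rt = rt, blocks = bcaches,
                    pdims = pdims, ln = ln, feat = feat, hr1 = hr1,
                    head = head))
}

encoder_backward <- function(params, spec, cache, dout) {
  g <- list()
  head <- cache$head
  if (head == "projection") {
    b2 <- dense_bw(cache$hr1, params[["h2.W"]], dout)
    g[["h2.W"]] <- b2$dW; g[["h2.b"]] <- b2$db
    dr1 <- relu_bw(cache$hr1, b2$dx)
    b1 <- dense_bw(cache$feat, params[["h1.W"]], dr1)
    g[["h1.W"]] <- b1$dW; g[["h1.b"]] <- b1$db
    dfeat <- b1$dx
  } else if (head == "classifier") {
    bc <- dense_bw(cache$feat, params[["cls.W"]], dout)
    g[["cls.W"]] <- bc$dW; g[["cls.b"]] <- bc$db
    dfeat <- bc$dx
  } else {
    dfeat <- dout
  }
  dh <- pool_bw(cache$pdims, lnorm_bw(cache$ln, dfeat))
  blocks <- encoder_layout(spec)
  for (i in rev(seq_along(blocks))) {
    bb <- block_bw(cache$blocks[[i]], params, blocks[[i]], dh)
    g <- c(g, bb$grads)
    dh <- bb$dx
  }
  drt <- relu_bw(cache$rt, dh)
  bnt <- inorm_bw(cache$nt, params[["t.g"]], drt)
  g[["t.g"]] <- bnt$dgamma
  g[["t.be"]] <- bnt$dbeta
  bct <- conv_bw(cache$x, params[["t.W"]], bnt$dx, 3L, spec$stem_stride,
                 need_dx = FALSE)
  g[["t.W"]] <- bct$dW
  g[["t.b"]] <- bct$db
  g
}

#' Embed one segment
#'
#' Runs a `k`-frame segment through the encoder. Global average pooling
#' makes the output width independent of the spatial input shape (any shape
#' with all axes >= 8 voxels is accepted).
#'
#' @param encoder An `fmri_encoder`.
#' @param segment 4-D array of exactly `k` frames.
#' @param head `"projection"` for the contrast-space vector (length
#'   `contrast_dim`), `"feature"` for the pooled feature vector (length
#'   `feature_dim`).
#' @return Numeric vector.
#' @export
encode <- function(encoder, segment, head = c("projection", "feature")) {
  stopifnot(inherits(encoder, "fmri_encoder"))
  head <- match.arg(head)
  encoder_forward(encoder$params, encoder$spec, segment, head)$out
}

#' Save / load a self-describing encoder checkpoint
#'
#' The checkpoint is a single serialized archive holding the weights plus a
#' JSON metadata block (spec, seed, epochs trained, loss curve), so a file
#' can be inspected without loading the weights.
#'
#' @param encoder An `fmri_encoder`.
#' @param path Destination file.
#' @param history Optional pretraining history `data.frame` to embed.
#' @return `path` invisibly ([save_checkpoint()]); an `fmri_encoder` with
#'   attribute `history` ([load_checkpoint()]); a list ([checkpoint_info()]).
#' @export
save_checkpoint <- function(encoder, path, history = NULL) {
  stopifnot(inherits(encoder, "fmri_encoder"))
  meta <- list(
    format = "fmricontrast-checkpoint", version = 1L,
    spec = unclass(encoder$spec),
    epochs = if (is.null(history)) 0L else nrow(history),
    loss = if (is.null(history)) numeric(0) else history$mean_loss)
  saveRDS(list(meta_json = jsonlite::toJSON(meta, auto_unbox = TRUE,
                                            digits = NA),
               params = encoder$params, history = history),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  meta <- jsonlite::fromJSON(obj$meta_json)
  if (!identical(meta$format, "fmricontrast-checkpoint"))
    stop_fc(path, " is not an fmricontrast checkpoint")
  spec <- do.call(encoder_spec, meta$spec[c("k", "base_channels",
                                            "stage_channels", "proj_hidden",
                                            "contrast_dim", "stem_stride",
                                            "seed")])
  enc <- structure(list(spec = spec, params = obj$params),
                   class = "fmri_encoder")
  attr(enc, "history") <- obj$history
  enc
}

#' @rdname save_checkpoint
#' @export
checkpoint_info <- function(path) {
  jsonlite::fromJSON(readRDS(path)$meta_json)
}
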