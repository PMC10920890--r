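#' 3D residual network configuration
#'
#' The network consumes `(n, n, n, channels)` voxel tensors and emits a
#' 20-way softmax over the masked residue's amino-acid identity. Layout:
#' stride-2 stem convolution (channels -> base_width), stride-2 downsample
#' convolution (base_width -> 2 * base_width), identity residual blocks
#' split across the two spatial stages, global average pooling and a dense
#' softmax head. All convolutions are 3x3x3.
#'
#' @param n_voxel Cube edge in voxels (default 20).
#' @param in_channels Input channels (default 9).
#' @param n_residual_blocks Total residual blocks (default 4), split evenly
#'   between the half- and quarter-resolution stages (extra block goes to
#'   the deeper stage).
#' @param base_width Stem width (default 32); the deep stage runs at twice
#'   this width.
#' @param n_classes Output classes (default 20).
#' @param seed Integer seed for deterministic He-normal initialization.
#' @return A list of class `model_config`.
#' @export
model_config <- function(n_voxel = 20L, in_channels = 9L,
                         n_residual_blocks = 4L, base_width = 32L,
                         n_classes = 20L, seed = 1L) {
  stopifnot(n_voxel >= 4, base_width >= 1, n_residual_blocks >= 0)
  structure(list(n_voxel = as.integer(n_voxel),
                 in_channels = as.integer(in_channels),
                 n_residual_blocks = as.integer(n_residual_blocks),
                 base_width = as.integer(base_width),
                 n_classes = as.integer(n_classes), seed = as.integer(seed)),
            class = "model_config")
}

#' Build a masked-residue 3D residual classifier
#'
#' @param config A [model_config()].
#' @return A `resnet3d` model object (list of layers with weights); use
#'   [predict_proba()], [train_model()], [evaluate_model()].
#' @export
build_model <- function(config = model_config()) {
  rng <- local_rng(config$seed)
  on.exit(restore_rng(rng))
  w <- config$base_width
  w2 <- 2L * w
  d0 <- config$n_voxel
  d1 <- as.integer(ceiling(d0 / 2))
  d2 <- as.integer(ceiling(d1 / 2))
  n_deep <- config$n_residual_blocks - config$n_residual_blocks %/% 2L
  n_shallow <- config$n_residual_blocks %/% 2L
  res_block <- function(width, d) {
    list(type = "res", conv1 = conv_init(width, width, d, 1L),
         conv2 = conv_init(width, width, d, 1L))
  }
  layers <- list(list(type = "conv_relu", conv = conv_init(config$in_channels, w, d0, 2L)))
  for (i in seq_len(n_shallow)) layers[[length(layers) + 1L]] <- res_block(w, d1)
  layers[[length(layers) + 1L]] <- list(type = "conv_relu", conv = conv_init(w, w2, d1, 2L))
  for (i in seq_len(n_deep)) layers[[length(layers) + 1L]] <- res_block(w2, d2)
  head_sd <- sqrt(2 / w2)
  model <- structure(
    list(config = config, layers = layers,
         head = list(W = matrix(stats::rnorm(w2 * config$n_classes, sd = head_sd),
                                w2, config$n_classes),
                     b = numeric(config$n_classes)),
         p_final = d2^3L,
         input_norm = list(center = numeric(config$in_channels),
                           scale = rep(1, config$in_channels))),
    class = "resnet3d")
  model
}

# per-channel standardization constants from (a subsample of) the training
# grids; stored on the model so inference applies the identical transform
fit_input_norm <- function(model, grids, max_grids = 200L) {
  idx <- if (length(grids) > max_grids)
    round(seq(1, length(grids), length.out = max_grids)) else seq_along(grids)
  P <- model$config$n_voxel^3L
  C <- model$config$in_channels
  s1 <- numeric(C); s2 <- numeric(C); n <- 0
  for (i in idx) {
    g <- grids[[i]]
    dim(g) <- c(P, C)
    s1 <- s1 + colSums(g)
    s2 <- s2 + colSums(g^2)
    n <- n + P
  }
  center <- s1 / n
  sd <- sqrt(pmax(s2 / n - center^2, 0))
  model$input_norm <- list(center = center, scale = pmax(sd, 1e-6))
  model
}

apply_input_norm <- function(model, X) {
  nrm <- model$input_norm
  if (is.null(nrm) || (all(nrm$center == 0) && all(nrm$scale == 1))) return(X)
  X <- sweep(X, 2, nrm$center, "-")
  sweep(X, 2, nrm$scale, "/")
}

#' Number of trainable parameters of a model
#' @param model A `resnet3d`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  n <- length(model$head$W) + length(model$head$b)
  for (ly in model$layers) {
    for (cv in ly[names(ly) %in% c("conv", "conv1", "conv2")]) {
      n <- n + length(cv$W) + length(cv$b)
    }
  }
  n
}

#' @export
print.resnet3d <- function(x, ...) {
  cat("<resnet3d> ", length(x$layers), " conv stages, ",
      format(n_parameters(x), big.mark = ","), " parameters\n", sep = "")
  invisible(x)
}

# full forward pass; keeps intermediates when `cache = TRUE` for backprop.
# X: (batch * n_voxel^3, in_channels) matrix
forward_pass <- function(model, X, batch, cache = FALSE) {
  acts <- list()
  h <- apply_input_norm(model, X)
  for (li in seq_along(model$layers)) {
    ly <- model$layers[[li]]
    if (ly$type == "conv_relu") {
      pre <- conv_forward(ly$conv, h, batch)
      out <- relu(pre)
      if (cache) acts[[li]] <- list(x = h, pre = pre)
      h <- out
    } else {
      pre1 <- conv_forward(ly$conv1, h, batch)
      a1 <- relu(pre1)
      pre2 <- conv_forward(ly$conv2, a1, batch)
      sum_ <- pre2 + h
      out <- relu(sum_)
      if (cache) acts[[li]] <- list(x = h, pre1 = pre1, a1 = a1, sum_ = sum_)
      h <- out
    }
  }
  pooled <- global_avg_pool(h, batch, model$p_final)
  logits <- sweep(pooled %*% model$head$W, 2, model$head$b, "+")
  probs <- softmax_rows(logits)
  if (cache) list(probs = probs, pooled = pooled, acts = acts, h_final = h)
  else probs
}

# backward pass for softmax cross-entropy; labels 1-based
backward_pass <- function(model, fwd, labels, batch) {
  n_cls <- model$config$n_classes
  dlogits <- fwd$probs
  dlogits[cbind(seq_len(batch), labels)] <-
    dlogits[cbind(seq_len(batch), labels)] - 1
  dlogits <- dlogits / batch
  grads <- list(head = list(W = crossprod(fwd$pooled, dlogits),
                            b = colSums(dlogits)),
                layers = vector("list", length(model$layers)))
  dpool <- tcrossprod(dlogits, model$head$W)
  P <- model$p_final
  dh <- dpool[rep(seq_len(batch), each = P), , drop = FALSE] / P
  dh[fwd$h_final <= 0] <- 0
  for (li in rev(seq_along(model$layers))) {
    ly <- model$layers[[li]]
    ac <- fwd$acts[[li]]
    if (ly$type == "conv_relu") {
      # dh arrives post-relu-mask already applied for this layer's output
      g <- conv_backward(ly$conv, ac$x, dh, batch)
      grads$layers[[li]] <- list(conv = list(W = g$dW, b = g$db))
      dh <- g$dX
    } else {
      dsum <- dh
      g2 <- conv_backward(ly$conv2, ac$a1, dsum, batch)
      da1 <- g2$dX
      da1[ac$pre1 <= 0] <- 0
      g1 <- conv_backward(ly$conv1, ac$x, da1, batch)
      grads$layers[[li]] <- list(conv1 = list(W = g1$dW, b = g1$db),
                                 conv2 = list(W = g2$dW, b = g2$db))
      dh <- g1$dX + dsum  # skip connection
    }
    if (li > 1L) {
      prev <- model$layers[[li - 1L]]
      pre_prev <- if (prev$type == "conv_relu") fwd$acts[[li - 1L]]$pre
                  else fwd$acts[[li - 1L]]$sum_
      dh[pre_prev <= 0] <- 0
    }
  }
  grads
}

#' Predict class probabilities for voxel grids
#'
#' @param model A `resnet3d`.
#' @param grids A list of voxel arrays `(n, n, n, channels)`, or a single
#'   such array.
#' @param batch_size Forward-pass batch size.
#' @return Matrix `(n_items, n_classes)` of softmax probabilities; columns
#'   named by [aa_alphabet()] when `n_classes == 20`.
#' @export
predict_proba <- function(model, grids, batch_size = 64L) {
  if (is.array(grids) && length(dim(grids)) == 4) grids <- list(grids)
  n <- length(grids)
  n_cls <- model$config$n_classes
  out <- matrix(NA_real_, n, n_cls)
  if (n_cls == 20L) colnames(out) <- aa_alphabet()
  P <- model$config$n_voxel^3L
  C <- model$config$in_channels
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    X <- matrix(0, length(idx) * P, C)
    for (j in seq_along(idx)) {
      g <- grids[[idx[j]]]
      dim(g) <- c(P, C)
      X[((j - 1L) * P + 1L):(j * P), ] <- g
    }
    out[idx, ] <- forward_pass(model, X, length(idx))
  }
  out
}
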