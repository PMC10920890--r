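#' Training configuration
#'
#' @param batch_size Mini-batch size (default 200).
#' @param max_epochs Maximum epochs; one checkpoint per epoch (default 8).
#' @param lr0 Initial learning rate (default 0.001).
#' @param lr_decay_constant Per-epoch exponential decay constant (default
#'   0.5; 0.3 is the usual alternative).
#' @param adaptive_drop_factor Multiplicative learning-rate drop applied
#'   when training accuracy stalls (default 0.25).
#' @param adaptive_improvement_threshold Required accuracy improvement, in
#'   percentage points, over one adaptive window (default 0.1).
#' @param adaptive_window Number of training instances per adaptive window
#'   (default 30000; 50000 and 60000 are the usual alternatives).
#' @param conv_weight_decay L2 weight decay applied to convolutional weights
#'   only (default 0.001).
#' @param seed Integer seed for shuffling.
#' @return A list of class `train_config`.
#' @export
train_config <- function(batch_size = 200L, max_epochs = 8L, lr0 = 0.001,
                         lr_decay_constant = 0.5, adaptive_drop_factor = 0.25,
                         adaptive_improvement_threshold = 0.1,
                         adaptive_window = 30000L, conv_weight_decay = 0.001,
                         seed = 1L) {
  stopifnot(batch_size >= 1, max_epochs >= 1, lr0 > 0, lr_decay_constant >= 0,
            adaptive_drop_factor > 0, adaptive_drop_factor <= 1,
            adaptive_window >= 1)
  structure(list(batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), lr0 = lr0,
                 lr_decay_constant = lr_decay_constant,
                 adaptive_drop_factor = adaptive_drop_factor,
                 adaptive_improvement_threshold = adaptive_improvement_threshold,
                 adaptive_window = as.integer(adaptive_window),
                 conv_weight_decay = conv_weight_decay,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Scheduled learning rate
#'
#' `lr = lr0 * exp(-decay * epoch) * drop_factor^n_drops`: an exponential
#' per-epoch decay from `lr0`, combined with an adaptive multiplicative drop
#' applied each time training accuracy fails to improve by the configured
#' threshold over one instance window.
#'
#' @param epoch 0-based epoch index.
#' @param n_drops Number of adaptive drops taken so far.
#' @param config A [train_config()].
#' @return Learning rate (scalar).
#' @export
lr_schedule <- function(epoch, n_drops = 0L, config = train_config()) {
  config$lr0 * exp(-config$lr_decay_constant * epoch) *
    config$adaptive_drop_factor^n_drops
}

# ---- Adam over the model's nested parameter list ------------------------

adam_state <- function(model) {
  zero_like <- function(p) {
    p$W[] <- 0; p$b[] <- 0
    p
  }
  walk <- function(f) {
    st <- list(head = f(model$head), layers = vector("list", length(model$layers)))
    for (li in seq_along(model$layers)) {
      ly <- model$layers[[li]]
      st$layers[[li]] <- lapply(ly[names(ly) %in% c("conv", "conv1", "conv2")],
                                function(cv) f(list(W = cv$W, b = cv$b)))
    }
    st
  }
  list(m = walk(zero_like), v = walk(zero_like), t = 0L)
}

adam_step <- function(model, grads, state, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(param, grad, m, v, decay) {
    gW <- grad$W + decay * param$W
    m$W <- beta1 * m$W + (1 - beta1) * gW
    v$W <- beta2 * v$W + (1 - beta2) * gW^2
    param$W <- param$W - lr * (m$W / bc1) / (sqrt(v$W / bc2) + eps)
    m$b <- beta1 * m$b + (1 - beta1) * grad$b
    v$b <- beta2 * v$b + (1 - beta2) * grad$b^2
    param$b <- param$b - lr * (m$b / bc1) / (sqrt(v$b / bc2) + eps)
    list(param = param, m = m, v = v)
  }
  r <- upd(model$head, grads$head, state$m$head, state$v$head, 0)
  model$head <- r$param; state$m$head <- r$m; state$v$head <- r$v
  for (li in seq_along(model$layers)) {
    for (nm in names(grads$layers[[li]])) {
      cv <- model$layers[[li]][[nm]]
      r <- upd(list(W = cv$W, b = cv$b), grads$layers[[li]][[nm]],
               state$m$layers[[li]][[nm]], state$v$layers[[li]][[nm]],
               weight_decay)
      model$layers[[li]][[nm]]$W <- r$param$W
      model$layers[[li]][[nm]]$b <- r$param$b
      state$m$layers[[li]][[nm]] <- r$m
      state$v$layers[[li]][[nm]] <- r$v
    }
  }
  list(model = model, state = state)
}

# grids list -> one (batch * P, C) matrix
stack_grids <- function(grids, idx, P, C) {
  X <- matrix(0, length(idx) * P, C)
  for (j in seq_along(idx)) {
    g <- grids[[idx[j]]]
    dim(g) <- c(P, C)
    X[((j - 1L) * P + 1L):(j * P), ] <- g
  }
  X
}

#' Train a masked-residue classifier
#'
#' Mini-batch Adam with softmax cross-entropy, L2 weight decay on
#' convolutional weights, the exponential + adaptive [lr_schedule()], an
#' in-memory checkpoint per epoch, and a full history log. Fully seeded:
#' identical seeds and data give identical trajectories.
#'
#' @param model A `resnet3d` from [build_model()].
#' @param dataset A `voxel_dataset` (or list with `grids` and 1-based
#'   `labels`).
#' @param config A [train_config()].
#' @param heldout Optional evaluation `voxel_dataset`; accuracy logged per
#'   epoch.
#' @param checkpoint_dir Optional directory; each epoch's weights are also
#'   saved there as `epoch_<k>.rds`.
#' @param normalize_input Standardize each input channel (center/scale
#'   constants fitted on the training grids and stored with the model, so
#'   inference applies the identical transform). Default `TRUE`.
#' @param verbose Print per-epoch progress.
#' @return List with `model` (final weights), `checkpoints` (per-epoch
#'   weight snapshots), and `history` tibble (`epoch`, `loss`,
#'   `train_accuracy`, `heldout_accuracy`, `lr`, `n_drops`).
#' @export
train_model <- function(model, dataset, config = train_config(),
                        heldout = NULL, checkpoint_dir = NULL,
                        normalize_input = TRUE, verbose = FALSE) {
  grids <- dataset$grids
  labels <- dataset$labels
  stopifnot(length(grids) >= 1, length(labels) == length(grids),
            all(labels >= 1), all(labels <= model$config$n_classes))
  P <- model$config$n_voxel^3L
  C <- model$config$in_channels
  n <- length(grids)
  if (normalize_input) model <- fit_input_norm(model, grids)
  state <- adam_state(model)
  rng <- local_rng(config$seed)
  on.exit(restore_rng(rng))
  n_drops <- 0L
  window_seen <- 0L
  window_correct <- 0L
  last_window_acc <- NA_real_
  history <- list()
  checkpoints <- list()
  for (epoch in seq_len(config$max_epochs) - 1L) {
    ord <- sample.int(n)
    ep_loss <- 0
    ep_correct <- 0L
    starts <- seq(1L, n, by = config$batch_size)
    for (bi in seq_along(starts)) {
      idx <- ord[starts[bi]:min(starts[bi] + config$batch_size - 1L, n)]
      B <- length(idx)
      X <- stack_grids(grids, idx, P, C)
      y <- labels[idx]
      fwd <- forward_pass(model, X, B, cache = TRUE)
      p_true <- fwd$probs[cbind(seq_len(B), y)]
      loss <- -mean(log(pmax(p_true, 1e-300)))
      if (!is.finite(loss)) {
        stop("NaN/Inf loss at epoch ", epoch, ", batch ", bi,
             " (first item index ", idx[1], ")")
      }
      pred <- max.col(fwd$probs, ties.method = "first")
      n_correct <- sum(pred == y)
      ep_loss <- ep_loss + loss * B
      ep_correct <- ep_correct + n_correct
      # adaptive monitor over training instances
      window_seen <- window_seen + B
      window_correct <- window_correct + n_correct
      if (window_seen >= config$adaptive_window) {
        acc <- 100 * window_correct / window_seen
        if (!is.na(last_window_acc) &&
            acc - last_window_acc < config$adaptive_improvement_threshold) {
          n_drops <- n_drops + 1L
        }
        last_window_acc <- acc
        window_seen <- 0L
        window_correct <- 0L
      }
      lr <- lr_schedule(epoch, n_drops, config)
      grads <- backward_pass(model, fwd, y, B)
      st <- adam_step(model, grads, state, lr, config$conv_weight_decay)
      model <- st$model
      state <- st$state
    }
    train_acc <- ep_correct / n
    ho_acc <- NA_real_
    if (!is.null(heldout)) {
      ho_acc <- evaluate_model(model, heldout)$overall_accuracy
    }
    history[[epoch + 1L]] <- tibble::tibble(
      epoch = epoch, loss = ep_loss / n, train_accuracy = train_acc,
      heldout_accuracy = ho_acc, lr = lr_schedule(epoch, n_drops, config),
      n_drops = n_drops)
    checkpoints[[epoch + 1L]] <- list(layers = model$layers, head = model$head,
                                      input_norm = model$input_norm)
    if (!is.null(checkpoint_dir)) {
      dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      saveRDS(checkpoints[[epoch + 1L]],
              file.path(checkpoint_dir, sprintf("epoch_%d.rds", epoch)))
    }
    if (verbose) {
      message(sprintf("epoch %d: loss %.4f train_acc %.3f heldout %.3f lr %.2e drops %d",
                      epoch, ep_loss / n, train_acc, ho_acc,
                      lr_schedule(epoch, n_drops, config), n_drops))
    }
  }
  list(model = model, checkpoints = checkpoints,
       history = dplyr::bind_rows(history))
}

#' Restore a checkpoint into a model
#'
#' @param model A `resnet3d` providing the architecture.
#' @param checkpoint One element of `train_model()$checkpoints`, or the path
#'   of an `epoch_<k>.rds` file.
#' @return The model with the checkpoint's weights.
#' @export
load_checkpoint <- function(model, checkpoint) {
  if (is.character(checkpoint)) checkpoint <- readRDS(checkpoint)
  model$layers <- checkpoint$layers
  model$head <- checkpoint$head
  if (!is.null(checkpoint$input_norm)) model$input_norm <- checkpoint$input_norm
  model
}

#' Evaluate wild-type accuracy, overall and per interface stratum
#'
#' Accuracy is the fraction of items whose argmax probability matches the
#' wild-type label, ties broken toward the lowest class index. Strata come
#' from the dataset metadata: `ligand-interface` and `nucleic-interface`
#' (interface kinds containing those classes) and `non-interface`. Empty
#' strata are reported as `NA`, not 0.
#'
#' @param model A `resnet3d` or a list of models (ensembled with
#'   [ensemble_predict_grids()]).
#' @param dataset A `voxel_dataset` with labels (and optionally metadata).
#' @return List of class `eval_report`: `overall_accuracy`, `n`, and
#'   `strata` (tibble with `stratum`, `accuracy`, `n`).
#' @export
evaluate_model <- function(model, dataset) {
  probs <- if (inherits(model, "resnet3d")) predict_proba(model, dataset$grids)
           else ensemble_predict_grids(model, dataset$grids)
  pred <- max.col(probs, ties.method = "first")
  y <- dataset$labels
  correct <- pred == y
  meta <- dataset$meta
  strata <- tibble::tibble(stratum = character(), accuracy = numeric(),
                           n = integer())
  if (!is.null(meta) && nrow(meta) == length(y)) {
    in_stratum <- list(
      `ligand-interface` = grepl("ligand", meta$interface_kind),
      `nucleic-interface` = grepl("nucleic", meta$interface_kind),
      `non-interface` = !meta$interface_flag
    )
    strata <- dplyr::bind_rows(lapply(names(in_stratum), function(nm) {
      sel <- in_stratum[[nm]]
      tibble::tibble(stratum = nm,
                     accuracy = if (any(sel)) mean(correct[sel]) else NA_real_,
                     n = sum(sel))
    }))
  }
  structure(list(overall_accuracy = mean(correct), n = length(y),
                 strata = strata, predictions = pred),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> overall wild-type accuracy %.3f (n = %d)\n",
              x$overall_accuracy, x$n))
  if (nrow(x$strata)) print(x$strata)
  invisible(x)
}
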