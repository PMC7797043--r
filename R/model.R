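#' Define a convolutional model architecture
#'
#' The default mirrors the full-scale architecture: a first convolutional
#' layer of 300 filters of width 19 (pool width 3, total zero-padding 18,
#' split symmetrically), two further conv layers, two fully connected hidden
#' layers with 30% dropout, and a sigmoid output over all features.
#'
#' @param conv_layers List of `c(filters, width, pool, pad)` vectors.
#' @param hidden Integer vector of fully connected hidden-layer widths.
#' @param dropout Dropout rate in `[0, 1)` applied to hidden layers
#'   (training only).
#' @param input_length Input window length in bp.
#' @param global_pool Insert a global max-pooling stage between the conv
#'   stack and the dense layers, so the classifier reads one
#'   position-invariant activation per filter. Off for the full-scale
#'   architecture; essential for learning from the few hundred sites of a
#'   desk-scale fixture, where a positional flatten has too many parameters
#'   per example to generalize.
#' @param batch_norm Per-filter batch normalization between each convolution
#'   and its ReLU (the convention of the architecture family this model
#'   follows); greatly accelerates filter learning.
#' @param rc_conv Strand-tied first conv layer: each filter scans both the
#'   forward and reverse-complement orientation of its weights and keeps the
#'   better per position. DNase-seq/ChIP-seq signal is strand-symmetric, so
#'   a motif and its reverse complement are the same evidence; weight tying
#'   encodes that directly and lets a single filter cover both strands.
#' @param conv_activation First-layer activation: `"relu"` (default) or
#'   `"exp"`, a saturating exponential that amplifies rare strong alignments
#'   so motif-like activations dominate pooling; markedly more robust filter
#'   learning on small training sets.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(conv_layers = list(c(300L, 19L, 3L, 18L),
                                          c(200L, 11L, 4L, 0L),
                                          c(200L, 7L, 4L, 0L)),
                       hidden = c(1000L, 1000L),
                       dropout = 0.3,
                       input_length = 1000L,
                       global_pool = FALSE,
                       batch_norm = TRUE,
                       rc_conv = FALSE,
                       conv_activation = c("relu", "exp")) {
  conv_activation <- match.arg(conv_activation)
  stopifnot(dropout >= 0, dropout < 1, length(hidden) >= 1)
  for (cl in conv_layers) stopifnot(length(cl) == 4L, all(cl[1:3] > 0))
  # shape check: pooled length must stay positive
  L <- input_length
  for (cl in conv_layers) {
    L <- L + cl[4] - cl[2] + 1L
    if (L <= 0) stop("conv layer output length <= 0; spec invalid")
    L <- L %/% cl[3]
    if (L <= 0) stop("pooled length reaches 0; spec invalid")
  }
  structure(list(conv_layers = conv_layers, hidden = hidden,
                 dropout = dropout, input_length = input_length,
                 global_pool = isTRUE(global_pool),
                 batch_norm = isTRUE(batch_norm),
                 rc_conv = isTRUE(rc_conv),
                 conv_activation = conv_activation),
            class = "model_spec")
}

#' Reduced architecture for desk-scale experiments
#'
#' One conv layer of 32 width-19 filters (pool 3, pad 18), a global
#' max-pooling readout, and two 64-unit hidden layers: small enough to train
#' on a laptop CPU in minutes yet able to learn planted 8-mer motifs from a
#' few hundred training sites.
#' @inheritParams model_spec
#' @param n_filters Number of first-layer filters.
#' @return `model_spec`.
#' @export
desk_model_spec <- function(n_filters = 32L, hidden = c(64L, 64L),
                            dropout = 0.3, input_length = 1000L,
                            global_pool = TRUE, batch_norm = TRUE,
                            rc_conv = FALSE, conv_activation = "exp") {
  model_spec(conv_layers = list(c(n_filters, 19L, 3L, 18L)),
             hidden = hidden, dropout = dropout,
             input_length = input_length, global_pool = global_pool,
             batch_norm = batch_norm, rc_conv = rc_conv,
             conv_activation = conv_activation)
}

#' Training configuration
#'
#' @param learning_rate RMSprop learning rate.
#' @param decay RMSprop squared-gradient decay.
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch cap.
#' @param patience Early-stopping patience: training halts once validation
#'   loss has not improved for this many consecutive epochs.
#' @param l2 L2 weight-decay coefficient on weight matrices (biases exempt);
#'   counters memorization by the wide flattened layer at desk scale.
#' @param momentum Momentum on the RMSprop-scaled step (0 disables).
#' @param seed Seed for minibatch shuffling and dropout masks.
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.002, decay = 0.98,
                         batch_size = 128L, max_epochs = 30L,
                         patience = 12L, l2 = 0, momentum = 0,
                         seed = 1L) {
  stopifnot(learning_rate > 0, decay > 0, decay < 1, batch_size >= 1,
            max_epochs >= 1, patience >= 1, l2 >= 0,
            momentum >= 0, momentum < 1)
  structure(list(learning_rate = learning_rate, decay = decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), l2 = l2,
                 momentum = momentum, seed = as.integer(seed)),
            class = "train_config")
}

conv_out_lengths <- function(spec) {
  L <- spec$input_length
  lens <- integer(0)
  for (cl in spec$conv_layers) {
    L <- (L + cl[4] - cl[2] + 1L) %/% cl[3]
    lens <- c(lens, L)
  }
  lens
}

#' Build an (untrained) model
#'
#' Parameters are drawn deterministically from `seed` (He-scaled normal
#' weights, zero biases), so two builds with the same seed produce identical
#' predictions.
#'
#' @param spec `model_spec`.
#' @param n_features Number of output features F.
#' @param seed Integer initialization seed.
#' @param feature_meta Optional data.frame of feature metadata (`feature`
#'   column required) fixing the model's output order.
#' @return Object of class `deepfun_model` with untrained parameters.
#' @export
build_model <- function(spec, n_features, seed = 1L, feature_meta = NULL) {
  stopifnot(inherits(spec, "model_spec"), n_features >= 1)
  set.seed(seed)
  conv_W <- list(); conv_b <- list()
  C <- 4L
  for (cl in spec$conv_layers) {
    fan_in <- C * cl[2]
    conv_W[[length(conv_W) + 1L]] <-
      matrix(stats::rnorm(cl[1] * fan_in, sd = sqrt(2 / fan_in)),
             nrow = cl[1])
    conv_b[[length(conv_b) + 1L]] <- numeric(cl[1])
    C <- cl[1]
  }
  lens <- conv_out_lengths(spec)
  flat <- if (isTRUE(spec$global_pool)) C else C * lens[length(lens)]
  dims <- c(flat, spec$hidden, n_features)
  dense_W <- list(); dense_b <- list()
  for (j in seq_len(length(dims) - 1L)) {
    # He scaling for ReLU layers; smaller scale for the sigmoid output so
    # initial logits stay near zero
    sd <- if (j == length(dims) - 1L) sqrt(0.1 / dims[j]) else
      sqrt(2 / dims[j])
    dense_W[[j]] <- matrix(stats::rnorm(dims[j + 1L] * dims[j], sd = sd),
                           nrow = dims[j + 1L])
    dense_b[[j]] <- numeric(dims[j + 1L])
  }
  if (is.null(feature_meta))
    feature_meta <- data.frame(feature = paste0("feature", seq_len(n_features)),
                               stringsAsFactors = FALSE)
  nfilt <- vapply(spec$conv_layers, `[`, integer(1), 1L)
  # exp-activated filters start in a sparse-firing regime: with unit-variance
  # normalized activations, beta = -3 leaves only ~0.1% of positions with
  # exp(z + beta) > 1, so rare strong alignments dominate pooling from the
  # first epoch
  beta0 <- if (identical(spec$conv_activation, "exp")) -3 else 0
  params <- list(conv_W = conv_W, conv_b = conv_b,
                 dense_W = dense_W, dense_b = dense_b,
                 bn_gamma = lapply(nfilt, function(k) rep(1, k)),
                 bn_beta = lapply(nfilt, function(k) rep(beta0, k)))
  structure(list(spec = spec, params = params,
                 bn_mean = lapply(nfilt, function(k) rep(0, k)),
                 bn_var = lapply(nfilt, function(k) rep(1, k)),
                 features = feature_meta,
                 n_features = as.integer(n_features),
                 log = NULL, best_epoch = NA_integer_, seed = seed),
            class = "deepfun_model")
}

#' @export
print.deepfun_model <- function(x, ...) {
  nf <- vapply(x$spec$conv_layers, `[`, integer(1), 1L)
  cat("deepfun_model:", paste(nf, collapse = "+"), "conv filters ->",
      paste(x$spec$hidden, collapse = "/"), "hidden ->",
      x$n_features, "features;",
      if (is.na(x$best_epoch)) "untrained" else
        paste0("trained (best epoch ", x$best_epoch, ")"), "\n")
  invisible(x)
}

spec_pools <- function(spec) as.integer(vapply(spec$conv_layers, `[`, integer(1), 3L))
spec_pads <- function(spec) as.integer(vapply(spec$conv_layers, `[`, integer(1), 4L))

#' Predict feature activity probabilities
#'
#' @param object Trained (or untrained) `deepfun_model`.
#' @param X A 4 x L x N one-hot array, a single 4 x L matrix, or a
#'   `deepfun_dataset` (its test split is used).
#' @param nullify Optional list `list(filter =, value =)` ablating one
#'   first-layer filter: its post-ReLU output map is replaced by `value`.
#' @param ... Unused.
#' @return N x F matrix of probabilities in (0, 1).
#' @export
predict.deepfun_model <- function(object, X, nullify = NULL, ...) {
  if (inherits(X, "deepfun_dataset")) X <- dataset_tensors(X, "test")$X
  if (is.matrix(X)) X <- array(X, dim = c(dim(X), 1L))
  if (dim(X)[1] != 4L || dim(X)[2] != object$spec$input_length)
    stop("input width mismatch: expected 4 x ", object$spec$input_length)
  p <- object$params
  nf <- if (is.null(nullify)) 0L else as.integer(nullify$filter)
  nv <- if (is.null(nullify)) 0 else as.numeric(nullify$value)
  probs <- cpp_predict(p$conv_W, p$conv_b, spec_pools(object$spec),
                       spec_pads(object$spec), p$dense_W, p$dense_b,
                       X, isTRUE(object$spec$batch_norm), p$bn_gamma,
                       p$bn_beta, object$bn_mean, object$bn_var,
                       nf, nv, isTRUE(object$spec$global_pool),
                       isTRUE(object$spec$rc_conv),
                       identical(object$spec$conv_activation, "exp"))
  out <- t(probs)
  colnames(out) <- object$features$feature
  out
}

#' Train a model with RMSprop and early stopping
#'
#' Minibatch RMSprop on mean binary cross-entropy across features. Minibatch
#' order and dropout masks are reshuffled each epoch from the config seed.
#' Training halts when the validation loss has not improved for
#' `config$patience` consecutive epochs (or at `max_epochs`); the returned
#' parameters are those of the best validation epoch.
#'
#' @param model `deepfun_model` from [build_model()].
#' @param dataset `deepfun_dataset` with non-empty train and validation
#'   splits, or a list with `X`/`y`/`val_X`/`val_y` tensors.
#' @param config `train_config`.
#' @param verbose Print per-epoch losses.
#' @return The trained `deepfun_model`, with `log` (data.frame of per-epoch
#'   train/validation loss) and `best_epoch` filled in.
#' @export
train_model <- function(model, dataset, config = train_config(),
                        verbose = FALSE) {
  stopifnot(inherits(model, "deepfun_model"), inherits(config, "train_config"))
  if (inherits(dataset, "deepfun_dataset")) {
    tr <- dataset_tensors(dataset, "train")
    va <- dataset_tensors(dataset, "validation")
    train_X <- tr$X; train_y <- tr$y; val_X <- va$X; val_y <- va$y
  } else {
    train_X <- dataset$X; train_y <- dataset$y
    val_X <- dataset$val_X; val_y <- dataset$val_y
  }
  n <- dim(train_X)[3]
  if (n == 0L || is.null(val_X) || dim(val_X)[3] == 0L)
    stop("train and validation splits must be non-empty")

  p <- model$params
  pools <- spec_pools(model$spec); pads <- spec_pads(model$spec)
  bn <- isTRUE(model$spec$batch_norm)
  bn_mean <- model$bn_mean; bn_var <- model$bn_var
  bn_momentum <- 0.9   # running-statistics smoothing
  cache <- rapply(p, function(x) x * 0, how = "replace")  # RMSprop state
  vel <- rapply(p, function(x) x * 0, how = "replace")    # momentum state
  drop_rate <- model$spec$dropout
  hidden_dims <- vapply(p$dense_W[-length(p$dense_W)], nrow, integer(1))

  set.seed(config$seed)
  best_val <- Inf; best_epoch <- NA_integer_; best_params <- p
  best_bn <- list(mean = bn_mean, var = bn_var)
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric())
  stale <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    epoch_loss <- 0; nb <- 0L
    for (s in starts) {
      idx <- perm[s:min(s + config$batch_size - 1L, n)]
      Xb <- train_X[, , idx, drop = FALSE]
      Yb <- t(train_y[idx, , drop = FALSE])
      masks <- lapply(hidden_dims, function(h) {
        if (drop_rate <= 0) matrix(1, h, length(idx)) else
          matrix(stats::rbinom(h * length(idx), 1L, 1 - drop_rate) /
                   (1 - drop_rate), h, length(idx))
      })
      g <- cpp_train_batch(p$conv_W, p$conv_b, pools, pads,
                           p$dense_W, p$dense_b, Xb, Yb, masks,
                           bn, p$bn_gamma, p$bn_beta,
                           isTRUE(model$spec$global_pool),
                           isTRUE(model$spec$rc_conv),
                           identical(model$spec$conv_activation, "exp"))
      if (!is.finite(g$loss))
        stop("NaN training loss at epoch ", epoch)
      l2 <- config$l2 %||% 0
      mom <- config$momentum %||% 0
      upd <- function(param, grad, cache, vel, decay_param = TRUE) {
        if (decay_param && l2 > 0) grad <- grad + l2 * param
        cache2 <- config$decay * cache + (1 - config$decay) * grad^2
        step <- config$learning_rate * grad / (sqrt(cache2) + 1e-8)
        vel2 <- mom * vel + step
        list(param = param - vel2, cache = cache2, vel = vel2)
      }
      for (l in seq_along(p$conv_W)) {
        u <- upd(p$conv_W[[l]], g$conv_dW[[l]], cache$conv_W[[l]],
                 vel$conv_W[[l]])
        p$conv_W[[l]] <- u$param; cache$conv_W[[l]] <- u$cache
        vel$conv_W[[l]] <- u$vel
        u <- upd(p$conv_b[[l]], as.numeric(g$conv_db[[l]]), cache$conv_b[[l]],
                 vel$conv_b[[l]], decay_param = FALSE)
        p$conv_b[[l]] <- u$param; cache$conv_b[[l]] <- u$cache
        vel$conv_b[[l]] <- u$vel
      }
      for (l in seq_along(p$dense_W)) {
        u <- upd(p$dense_W[[l]], g$dense_dW[[l]], cache$dense_W[[l]],
                 vel$dense_W[[l]])
        p$dense_W[[l]] <- u$param; cache$dense_W[[l]] <- u$cache
        vel$dense_W[[l]] <- u$vel
        u <- upd(p$dense_b[[l]], as.numeric(g$dense_db[[l]]), cache$dense_b[[l]],
                 vel$dense_b[[l]], decay_param = FALSE)
        p$dense_b[[l]] <- u$param; cache$dense_b[[l]] <- u$cache
        vel$dense_b[[l]] <- u$vel
      }
      if (bn) {
        for (l in seq_along(p$bn_gamma)) {
          u <- upd(p$bn_gamma[[l]], as.numeric(g$bn_dgamma[[l]]),
                   cache$bn_gamma[[l]], vel$bn_gamma[[l]],
                   decay_param = FALSE)
          p$bn_gamma[[l]] <- u$param; cache$bn_gamma[[l]] <- u$cache
          vel$bn_gamma[[l]] <- u$vel
          u <- upd(p$bn_beta[[l]], as.numeric(g$bn_dbeta[[l]]),
                   cache$bn_beta[[l]], vel$bn_beta[[l]],
                   decay_param = FALSE)
          p$bn_beta[[l]] <- u$param; cache$bn_beta[[l]] <- u$cache
          vel$bn_beta[[l]] <- u$vel
          bn_mean[[l]] <- bn_momentum * bn_mean[[l]] +
            (1 - bn_momentum) * as.numeric(g$bn_batch_mean[[l]])
          bn_var[[l]] <- bn_momentum * bn_var[[l]] +
            (1 - bn_momentum) * as.numeric(g$bn_batch_var[[l]])
        }
      }
      epoch_loss <- epoch_loss + g$loss; nb <- nb + 1L
    }
    val_loss <- cpp_loss(p$conv_W, p$conv_b, pools, pads,
                         p$dense_W, p$dense_b, val_X, t(val_y),
                         bn, p$bn_gamma, p$bn_beta, bn_mean, bn_var,
                         isTRUE(model$spec$global_pool),
                         isTRUE(model$spec$rc_conv),
                         identical(model$spec$conv_activation, "exp"))
    log <- rbind(log, data.frame(epoch = epoch,
                                 train_loss = epoch_loss / nb,
                                 val_loss = val_loss))
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f", epoch,
                      epoch_loss / nb, val_loss))
    if (val_loss < best_val - 1e-12) {
      best_val <- val_loss; best_epoch <- epoch; best_params <- p
      best_bn <- list(mean = bn_mean, var = bn_var)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= config$patience) break
    }
  }
  model$params <- best_params
  model$bn_mean <- best_bn$mean
  model$bn_var <- best_bn$var
  model$log <- log
  model$best_epoch <- best_epoch
  model$train_config <- config
  model
}

#' Area under the ROC curve per feature
#'
#' AUC is computed as the normalized Mann-Whitney U statistic via midranks,
#' crediting ties 0.5; features with an empty class are flagged `NA`.
#'
#' @param scores N x F matrix (or vector) of predicted probabilities.
#' @param labels N x F binary matrix (or vector).
#' @return data.frame with feature, auc, n_pos, n_neg.
#' @export
evaluate_auc <- function(scores, labels) {
  if (is.vector(scores)) scores <- matrix(scores, ncol = 1L)
  if (is.vector(labels)) labels <- matrix(labels, ncol = 1L)
  if (!all(dim(scores) == dim(labels)))
    stop("scores and labels dimensions differ")
  feats <- colnames(scores) %||% paste0("feature", seq_len(ncol(scores)))
  res <- lapply(seq_len(ncol(scores)), function(j) {
    y <- labels[, j]; s <- scores[, j]
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    auc <- if (n1 == 0 || n0 == 0) NA_real_ else {
      r <- rank(s)
      (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }
    data.frame(feature = feats[j], auc = auc, n_pos = n1, n_neg = n0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Save / load a model checkpoint
#' @param model `deepfun_model`.
#' @param path File path (`.rds`).
#' @return `path` (save) or the model (load).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "deepfun_model"))
  m
}
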