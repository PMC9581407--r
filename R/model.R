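#' Model configuration for the two-channel window classifier
#'
#' The classifier is a compact convolutional network: three blocks of
#' `convolution (3x3, pad 1) -> batch normalization -> ReLU -> dropout ->
#' average pooling (2x2, stride 2)`, a flatten, two fully connected layers
#' of `fc_width` units (each with batch normalization and ReLU), and a
#' single sigmoid output unit giving the loop probability. With the default
#' 23-bin window the spatial size shrinks 23 -> 11 -> 5 -> 2 across the
#' three blocks.
#'
#' @param window_size Input window size in bins (odd; default 23).
#' @param in_channels Number of input channels (default 2: Hi-C +
#'   accessibility).
#' @param filters Integer vector of length 3: feature maps per conv block.
#' @param fc_width Width of the two fully connected layers (default 64).
#' @param dropout Dropout rate in `[0, 1)` applied after each conv block
#'   (default 0.2).
#' @param seed Seed for parameter initialization.
#' @return A `model_config` list.
#' @export
model_config <- function(window_size = 23, in_channels = 2,
                         filters = c(4, 8, 16), fc_width = 64,
                         dropout = 0.2, seed = 1) {
  half_width(window_size)
  if (window_size < 9) {
    stop("`window_size` must be at least 9 (three 2x pooling stages)", call. = FALSE)
  }
  if (length(filters) != 3 || any(filters < 1)) {
    stop("`filters` must give exactly three positive conv block widths", call. = FALSE)
  }
  assert_scalar_number(dropout, "dropout", 0, 1 - 1e-12)
  assert_scalar_number(fc_width, "fc_width", 1)
  structure(list(window_size = as.integer(window_size),
                 in_channels = as.integer(in_channels),
                 filters = as.integer(filters),
                 fc_width = as.integer(fc_width),
                 dropout = dropout, seed = as.integer(seed)),
            class = "model_config")
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 0.001).
#' @param batch_size Mini-batch size (default 128).
#' @param max_epochs Epoch budget (default 100).
#' @param patience Early-stopping patience in epochs without validation
#'   PR-AUC improvement (default 15).
#' @param val_fraction Fraction of non-test chromosomes held out for
#'   validation in [loco_split()] (default 0.2).
#' @param seed Seed for shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 128,
                         max_epochs = 100, patience = 15, val_fraction = 0.2,
                         seed = 1) {
  assert_scalar_number(learning_rate, "learning_rate", lower = 1e-12)
  assert_scalar_number(batch_size, "batch_size", lower = 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "train_config")
}

he_mat <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

#' Initialize an untrained classifier
#'
#' Parameters are drawn deterministically from `config$seed` (He-scaled
#' normal weights, zero biases, unit batch-norm scale).
#'
#' @param config A [model_config()].
#' @return An object of class `loop_cnn`.
#' @export
init_model <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  f <- config$filters
  chans <- c(config$in_channels, f)
  params <- with_seed(config$seed, {
    conv <- lapply(1:3, function(l) {
      fan_in <- chans[l] * 9
      list(W = he_mat(chans[l + 1], fan_in, fan_in),
           b = numeric(chans[l + 1]),
           gamma = rep(1, chans[l + 1]), beta = numeric(chans[l + 1]),
           rmean = numeric(chans[l + 1]), rvar = rep(1, chans[l + 1]))
    })
    fcw <- config$fc_width
    flat <- f[3] * (config$window_size %/% 8)^2
    fc_in <- c(flat, fcw)
    fc <- lapply(1:2, function(l) {
      list(W = he_mat(fcw, fc_in[l], fc_in[l]), b = numeric(fcw),
           gamma = rep(1, fcw), beta = numeric(fcw),
           rmean = numeric(fcw), rvar = rep(1, fcw))
    })
    out <- list(W = matrix(stats::rnorm(fcw, sd = sqrt(1 / fcw)), 1, fcw),
                b = 0)
    list(conv = conv, fc = fc, out = out)
  })
  structure(list(config = config, params = params, history = NULL,
                 trained = FALSE, best_epoch = NA_integer_,
                 normalization = "log10(1+x) / (1+max) per window"),
            class = "loop_cnn")
}

#' Number of learnable parameters
#'
#' @param model A `loop_cnn`.
#' @return Integer count of weights, biases and batch-norm scale/shift terms.
#' @export
n_params <- function(model) {
  cnt <- function(layer) {
    length(layer$W) + length(layer$b) +
      length(layer$gamma %||% numeric(0)) + length(layer$beta %||% numeric(0))
  }
  sum(vapply(model$params$conv, cnt, 0)) +
    sum(vapply(model$params$fc, cnt, 0)) +
    cnt(model$params$out)
}

#' Binary cross-entropy loss
#'
#' Mean over samples of `-y * log(p) - (1 - y) * log(1 - p)` with natural
#' logarithm; predictions are clamped to `[1e-7, 1 - 1e-7]`.
#'
#' @param labels Vector of 0/1 labels.
#' @param predictions Vector of probabilities in `(0, 1)`.
#' @return A non-negative scalar.
#' @export
#' @examples
#' bce_loss(0, 0.5)  # log(2)
bce_loss <- function(labels, predictions) {
  if (length(labels) != length(predictions)) {
    stop("`labels` and `predictions` must have equal length", call. = FALSE)
  }
  p <- pmin(pmax(predictions, 1e-7), 1 - 1e-7)
  mean(-labels * log(p) - (1 - labels) * log(1 - p))
}

#' Leave-one-chromosome-out split
#'
#' The test set is the single held-out chromosome; the remaining
#' chromosomes are shuffled by `seed` and `round(val_fraction * m)` of them
#' (at least one, when two or more remain) go to validation, the rest to
#' training.
#'
#' @param chromosomes Character vector of chromosome names.
#' @param test_chrom The held-out chromosome.
#' @param val_fraction Validation share of the remaining chromosomes.
#' @param seed Shuffle seed.
#' @return A list with `train`, `validation`, `test` character vectors;
#'   disjoint, jointly covering the input.
#' @export
loco_split <- function(chromosomes, test_chrom, val_fraction = 0.2, seed = 1) {
  if (!test_chrom %in% chromosomes) {
    stop(sprintf("test chromosome '%s' not in the chromosome list", test_chrom),
         call. = FALSE)
  }
  assert_scalar_number(val_fraction, "val_fraction", 1e-12, 1 - 1e-12)
  rest <- setdiff(chromosomes, test_chrom)
  m <- length(rest)
  n_val <- if (m >= 2) max(1L, round(val_fraction * m)) else 0L
  shuffled <- with_seed(seed, sample(rest))
  list(train = sort(shuffled[seq_len(m - n_val) + n_val]),
       validation = sort(shuffled[seq_len(n_val)]),
       test = test_chrom)
}

# --- Adam over the nested parameter list ------------------------------------

trainable_keys <- c("W", "b", "gamma", "beta")

map_params <- function(params, f) {
  list(conv = lapply(params$conv, function(l) {
         l[trainable_keys[trainable_keys %in% names(l)]] <-
           lapply(trainable_keys[trainable_keys %in% names(l)], function(k) f(l[[k]]))
         l
       }),
       fc = lapply(params$fc, function(l) {
         l[trainable_keys] <- lapply(trainable_keys, function(k) f(l[[k]]))
         l
       }),
       out = list(W = f(params$out$W), b = f(params$out$b)))
}

adam_init <- function(params) {
  zero <- function(x) x * 0
  list(m = map_params(params, zero), v = map_params(params, zero), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  walk_layer <- function(pl, gl, ml, vl) {
    for (k in intersect(trainable_keys, names(gl))) {
      r <- upd(pl[[k]], gl[[k]], ml[[k]], vl[[k]])
      pl[[k]] <- r$p; ml[[k]] <- r$m; vl[[k]] <- r$v
    }
    list(p = pl, m = ml, v = vl)
  }
  for (l in 1:3) {
    r <- walk_layer(params$conv[[l]], grads$conv[[l]],
                    state$m$conv[[l]], state$v$conv[[l]])
    params$conv[[l]] <- r$p; state$m$conv[[l]] <- r$m; state$v$conv[[l]] <- r$v
  }
  for (l in 1:2) {
    r <- walk_layer(params$fc[[l]], grads$fc[[l]],
                    state$m$fc[[l]], state$v$fc[[l]])
    params$fc[[l]] <- r$p; state$m$fc[[l]] <- r$m; state$v$fc[[l]] <- r$v
  }
  r <- walk_layer(params$out, grads$out, state$m$out, state$v$out)
  params$out <- r$p; state$m$out <- r$m; state$v$out <- r$v
  list(params = params, state = state)
}

#' Train the classifier
#'
#' Minimizes [bce_loss()] with Adam (default betas) over shuffled
#' mini-batches, evaluating the validation PR-AUC each epoch. The
#' parameters with the best validation PR-AUC are kept; training stops at
#' `max_epochs` or after `patience` epochs without improvement. The entire
#' run, including dropout and shuffling, is reproducible from
#' `tc$seed`.
#'
#' @param model An untrained or trained `loop_cnn`.
#' @param train_ds,val_ds `loop_dataset` objects; the training set must
#'   contain both classes.
#' @param tc A [train_config()].
#' @return The trained `loop_cnn`, with a per-epoch `history` tibble.
#' @export
train_model <- function(model, train_ds, val_ds, tc = train_config()) {
  stopifnot(inherits(model, "loop_cnn"), inherits(train_ds, "loop_dataset"),
            inherits(val_ds, "loop_dataset"))
  if (length(unique(train_ds$label)) < 2) {
    stop("training set must contain both classes", call. = FALSE)
  }
  if (length(val_ds$label) == 0) stop("validation set is empty", call. = FALSE)
  params <- model$params
  state <- adam_init(params)
  p_drop <- model$config$dropout
  n <- length(train_ds$label)
  bs <- min(tc$batch_size, n)
  f <- model$config$filters
  # pre-pool spatial sizes of the three conv blocks (dropout mask lengths)
  hsz <- model$config$window_size %/% c(1L, 2L, 4L)

  history <- vector("list", tc$max_epochs)
  best <- list(prauc = -Inf, loss = Inf, params = params, epoch = NA_integer_)
  stale <- 0L
  epochs_run <- 0L

  with_seed(tc$seed, {
    for (epoch in seq_len(tc$max_epochs)) {
      idx <- sample(n)
      ep_loss <- 0; ep_n <- 0L
      for (start in seq(1, n, by = bs)) {
        bidx <- idx[start:min(start + bs - 1, n)]
        nb <- length(bidx)
        xb <- train_ds$x[, , , bidx, drop = FALSE]
        yb <- train_ds$label[bidx]
        dropu <- lapply(1:3, function(l) stats::runif(f[l] * hsz[l]^2 * nb))
        res <- cpp_cnn_train_batch(params, xb, yb, dropu, p_drop)
        st <- adam_step(params, res$grads, state, tc$learning_rate)
        params <- st$params; state <- st$state
        ep_loss <- ep_loss + res$loss * nb; ep_n <- ep_n + nb
      }
      # calibrate batch-norm inference statistics on the full training set
      # (dropout-free pass); exact rather than a running average, which is
      # affordable at these dataset sizes and keeps inference faithful to
      # the training-time normalization
      params <- bn_calibrate(params, train_ds, f, hsz)
      val_probs <- infer_probs(params, val_ds$x)
      val_loss <- bce_loss(val_ds$label, val_probs)
      val_prauc <- pr_auc(val_ds$label, val_probs)
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = ep_loss / ep_n,
        val_loss = val_loss, val_prauc = val_prauc)
      epochs_run <- epoch
      # best validation PR-AUC checkpoint; exact ties (PR-AUC saturates
      # quickly on separable data) are resolved by validation loss, which
      # keeps improving as the decision margin grows
      if (val_prauc > best$prauc ||
          (val_prauc == best$prauc && val_loss < best$loss)) {
        best <- list(prauc = val_prauc, loss = val_loss, params = params,
                     epoch = epoch)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= tc$patience) break
      }
    }
  })
  model$params <- best$params
  model$history <- dplyr::bind_rows(history[seq_len(epochs_run)])
  model$trained <- TRUE
  model$best_epoch <- best$epoch
  model$train_config <- tc
  model
}

# set batch-norm inference statistics from a dropout-free pass over a dataset
bn_calibrate <- function(params, ds, filters, hsz) {
  n <- length(ds$label)
  du <- lapply(1:3, function(l) rep(1, filters[l] * hsz[l]^2 * n))
  res <- cpp_cnn_train_batch(params, ds$x, ds$label, du, 0)
  for (l in 1:3) {
    params$conv[[l]]$rmean <- as.numeric(res$bn$conv[[l]]$mean)
    params$conv[[l]]$rvar <- as.numeric(res$bn$conv[[l]]$var)
  }
  for (l in 1:2) {
    params$fc[[l]]$rmean <- as.numeric(res$bn$fc[[l]]$mean)
    params$fc[[l]]$rvar <- as.numeric(res$bn$fc[[l]]$var)
  }
  params
}

infer_probs <- function(params, x, chunk = 128L) {
  n <- dim(x)[4]
  if (n <= chunk) return(as.numeric(cpp_cnn_infer(params, x)))
  out <- numeric(n)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    out[idx] <- cpp_cnn_infer(params, x[, , , idx, drop = FALSE])
  }
  out
}

#' Predict loop probabilities for windows
#'
#' Runs the network in inference mode (dropout off, batch-norm running
#' statistics), so the output is deterministic and independent of how
#' samples are batched.
#'
#' @param object A `loop_cnn`.
#' @param newdata A `loop_dataset` or an array `w x w x 2 x n`.
#' @param ... Unused.
#' @return Numeric vector of probabilities in `(0, 1)`.
#' @export
predict.loop_cnn <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "loop_dataset")) newdata$x else newdata
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
  if (dim(x)[1] != object$config$window_size ||
      dim(x)[3] != object$config$in_channels) {
    stop("window shape does not match the model configuration", call. = FALSE)
  }
  infer_probs(object$params, x)
}

#' @export
print.loop_cnn <- function(x, ...) {
  cat(sprintf("<loop_cnn> %s, %dx%d x %d channels, filters %s, %d parameters\n",
              if (x$trained) "trained" else "untrained",
              x$config$window_size, x$config$window_size, x$config$in_channels,
              paste(x$config$filters, collapse = "/"), n_params(x)))
  if (x$trained) {
    cat(sprintf("  best epoch %d, validation PR-AUC %.4f\n", x$best_epoch,
                max(x$history$val_prauc)))
  }
  invisible(x)
}

#' Tidy the training history of a classifier
#'
#' @param x A trained `loop_cnn`.
#' @param ... Unused.
#' @return A tibble with one row per epoch: `epoch`, `train_loss`,
#'   `val_loss`, `val_prauc`.
#' @export
tidy.loop_cnn <- function(x, ...) {
  if (is.null(x$history)) {
    stop("model has no training history yet", call. = FALSE)
  }
  x$history
}

#' One-row summary of a trained classifier
#'
#' @param x A `loop_cnn`.
#' @param ... Unused.
#' @return A one-row tibble: parameter count, epochs run, best epoch and
#'   its validation PR-AUC, final training loss.
#' @export
glance.loop_cnn <- function(x, ...) {
  tibble::tibble(
    n_params = n_params(x),
    trained = x$trained,
    epochs = if (is.null(x$history)) 0L else nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_prauc = if (is.null(x$history)) NA_real_ else max(x$history$val_prauc),
    final_train_loss = if (is.null(x$history)) NA_real_ else
      x$history$train_loss[nrow(x$history)])
}

#' Plot training curves
#'
#' @param object A trained `loop_cnn`.
#' @param ... Unused.
#' @return A ggplot of per-epoch losses and validation PR-AUC.
#' @export
autoplot.loop_cnn <- function(object, ...) {
  h <- tidy.loop_cnn(object) |>
    tidyr::pivot_longer(-"epoch", names_to = "metric", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "Training history") +
    ggplot2::theme_minimal()
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single-file archive of the parameters, the model
#' configuration, the window-normalization identifier and the training
#' history.
#'
#' @param model A `loop_cnn`.
#' @param path Output path.
#' @return `save_model` returns the path invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "loop_cnn"))
  m
}
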