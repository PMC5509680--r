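#' Nine-layer network specification
#'
#' The patch classifier: two 5x5 convolutional layers followed by a max
#' pooling layer, then two smaller 3x3 convolutional layers each followed
#' by max pooling, then a hidden fully connected layer and the two-way
#' softmax output layer — nine layers in all
#' (conv, conv, pool, conv, pool, conv, pool, fc, fc). Feature counts start
#' at 24 and double per convolutional layer (24, 48, 96, 192), 360 filters
#' in total. Convolutions use stride one and full padding (output edge =
#' input edge + kernel - 1); pooling uses a 2x2 window with stride two.
#' Leaky rectifier nonlinearities everywhere except the softmax output;
#' dropout 1/3 after each pooling layer and 1/2 after the hidden fully
#' connected layer.
#'
#' @param conv_filters feature counts of the four convolutional layers.
#' @param conv_kernels kernel edges of the four convolutional layers.
#' @param pool_stride max-pooling stride (and window edge).
#' @param fc_width width of the hidden fully connected layer.
#' @param dropout_fc,dropout_pool dropout probabilities.
#' @param leaky_slope negative-side slope of the leaky rectifier.
#' @param n_classes output classes (tumour / non-tumour).
#' @param padding "full" (default) or "same".
#' @return Object of class `network_spec`.
#' @export
network_spec <- function(conv_filters = c(24, 48, 96, 192),
                         conv_kernels = c(5, 5, 3, 3),
                         pool_stride = 2,
                         fc_width = 256,
                         dropout_fc = 1 / 2,
                         dropout_pool = 1 / 3,
                         leaky_slope = 0.01,
                         n_classes = 2,
                         padding = c("full", "same")) {
  if (length(conv_filters) != 4L || length(conv_kernels) != 4L) {
    stopf("four convolutional layers are required")
  }
  padding <- match.arg(padding)
  structure(
    list(conv_filters = as.integer(conv_filters),
         conv_kernels = as.integer(conv_kernels),
         pool_stride = as.integer(pool_stride),
         fc_width = as.integer(fc_width),
         dropout_fc = dropout_fc, dropout_pool = dropout_pool,
         leaky_slope = leaky_slope, n_classes = as.integer(n_classes),
         padding = padding),
    class = "network_spec"
  )
}

#' Spatial size trace through the network
#'
#' @param patch_edge input patch edge M.
#' @param spec a [network_spec()].
#' @return Named integer vector of the spatial edge after each
#'   convolution/pooling stage (layer order conv, conv, pool, conv, pool,
#'   conv, pool). Errors, naming the failing layer, if any stage collapses
#'   below one voxel.
#' @export
layer_trace <- function(patch_edge, spec = network_spec()) {
  k <- spec$conv_kernels
  grow <- function(s, kk) if (spec$padding == "full") s + kk - 1L else s
  s <- as.integer(patch_edge)
  out <- c(input = s)
  stages <- list(c("conv1", 1), c("conv2", 2), c("pool1", 0), c("conv3", 3),
                 c("pool2", 0), c("conv4", 4), c("pool3", 0))
  for (st in stages) {
    nm <- st[1]
    i <- as.integer(st[2])
    s <- if (i > 0) grow(s, k[i]) else s %/% spec$pool_stride
    if (s < 1L) {
      stopf("patch edge %d is incompatible with the pooling chain: layer %s would see a %d-voxel map",
            patch_edge, nm, s)
    }
    out[nm] <- s
  }
  out
}

#' Build an untrained patch classifier
#'
#' Instantiates the nine-layer network for a given patch edge: He-scaled
#' Gaussian initialization of all weights, zero biases. The model maps an
#' M x M x 3 tile to a two-way probability vector (softmax output).
#'
#' @param spec a [network_spec()].
#' @param patch_edge patch edge M (odd).
#' @param n_channels input channels (3 MR sequences).
#' @param seed initialization seed.
#' @return Object of class `mparseg_model`.
#' @export
build_network <- function(spec = network_spec(), patch_edge = 21,
                          n_channels = 3, seed = 1L) {
  trace <- layer_trace(patch_edge, spec)
  f <- spec$conv_filters
  k <- spec$conv_kernels
  cin <- c(n_channels, f[1:3])
  flat_dim <- as.integer(trace[["pool3"]]^2 * f[4])
  with_seed(seed, {
    he <- function(dims, fan_in) array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
    params <- list()
    for (i in 1:4) {
      params[[paste0("W", i)]] <- he(c(k[i], k[i], cin[i], f[i]),
                                     k[i]^2 * cin[i])
      params[[paste0("b", i)]] <- numeric(f[i])
    }
    params$Wf1 <- matrix(rnorm(spec$fc_width * flat_dim, 0,
                               sqrt(2 / flat_dim)), spec$fc_width, flat_dim)
    params$bf1 <- numeric(spec$fc_width)
    params$Wf2 <- matrix(rnorm(spec$n_classes * spec$fc_width, 0,
                               sqrt(2 / spec$fc_width)),
                         spec$n_classes, spec$fc_width)
    params$bf2 <- numeric(spec$n_classes)
    structure(
      list(spec = spec, patch_edge = as.integer(patch_edge),
           n_channels = as.integer(n_channels), trace = trace,
           flat_dim = flat_dim, params = params, history = NULL),
      class = "mparseg_model"
    )
  })
}

#' @export
print.mparseg_model <- function(x, ...) {
  cat(sprintf(
    "<mparseg_model> patch %dx%dx%d, filters %s (total %d), fc %d, trained: %s\n",
    x$patch_edge, x$patch_edge, x$n_channels,
    paste(x$spec$conv_filters, collapse = "/"), sum(x$spec$conv_filters),
    x$spec$fc_width, if (is.null(x$history)) "no" else "yes"
  ))
  invisible(x)
}

#' Total number of convolutional filters
#'
#' @param spec a [network_spec()].
#' @return Integer, the summed feature counts of the convolutional layers
#'   (360 for the default specification).
#' @export
total_filters <- function(spec = network_spec()) sum(spec$conv_filters)

#' Training configuration
#'
#' @param lr Adadelta learning rate eta (default 0.001, as specified for
#'   the full-scale problem; at desk scale, with orders of magnitude fewer
#'   optimizer steps, the Adadelta reference value 1.0 is appropriate).
#' @param rho Adadelta decay (default 0.9).
#' @param eps Adadelta conditioning constant.
#' @param l2 small L2 regularization coefficient on the weights.
#' @param batch_size minibatch size.
#' @param patience early-stopping patience in epochs (default 5).
#' @param improvement_tol minimum test-cost improvement that counts
#'   (default 1e-3): training stops once no improvement larger than this is
#'   seen for `patience` consecutive epochs.
#' @param train_fraction fraction of the discovery set used for training
#'   (the rest monitors overfitting).
#' @param max_epochs epoch cap.
#' @param seed governs parameter shuffling and dropout.
#' @param verbose print one line per epoch.
#' @return Object of class `train_config`.
#' @export
train_config <- function(lr = 0.001, rho = 0.9, eps = 1e-6, l2 = 1e-4,
                         batch_size = 128, patience = 5,
                         improvement_tol = 1e-3, train_fraction = 0.8,
                         max_epochs = 200, seed = 1L, verbose = FALSE) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stopf("train_fraction must be in (0, 1)")
  }
  if (patience < 1) stopf("patience must be >= 1")
  structure(
    list(lr = lr, rho = rho, eps = eps, l2 = l2,
         batch_size = as.integer(batch_size), patience = as.integer(patience),
         improvement_tol = improvement_tol, train_fraction = train_fraction,
         max_epochs = as.integer(max_epochs), seed = as.integer(seed),
         verbose = isTRUE(verbose)),
    class = "train_config"
  )
}

#' Early-stopping rule on a test-cost sequence
#'
#' Pure function of the per-epoch test costs: training stops at the first
#' epoch `e` such that none of the last `patience` epochs improved the cost
#' by more than `tol` (improvement at epoch `e` is `cost[e-1] - cost[e]`;
#' the first epoch counts as an infinite improvement).
#'
#' @param test_costs numeric vector of per-epoch test costs.
#' @param patience number of consecutive non-improving epochs required.
#' @param tol improvement threshold (default 1e-3).
#' @return The stopping epoch, or `NA` if the rule has not fired yet.
#' @export
early_stop_epoch <- function(test_costs, patience = 5, tol = 1e-3) {
  n <- length(test_costs)
  if (n < patience) return(NA_integer_)
  imp <- c(Inf, -diff(test_costs))
  bad <- imp <= tol
  for (e in seq(patience, n)) {
    if (all(bad[(e - patience + 1):e])) return(e)
  }
  NA_integer_
}

#' Split the discovery patches into training and test sets
#'
#' Disjoint, exhaustive, label-stratified split: each class is split at
#' `train_fraction`, so class balance is preserved (within 1%) in both
#' subsets.
#'
#' @param patchset a `patch_set`.
#' @param train_fraction training share (default 0.8).
#' @param seed shuffling seed.
#' @return List with elements `train` and `test` (both `patch_set`).
#' @export
split_discovery <- function(patchset, train_fraction = 0.8, seed = 1L) {
  stopifnot(inherits(patchset, "patch_set"))
  n <- length(patchset$labels)
  if (n == 0L) stopf("empty patch set")
  with_seed(seed, {
    train_idx <- integer(0)
    for (cl in sort(unique(patchset$labels))) {
      ci <- which(patchset$labels == cl)
      k <- round(train_fraction * length(ci))
      train_idx <- c(train_idx, ci[sample.int(length(ci), k)])
    }
    train_idx <- sort(train_idx)
    test_idx <- setdiff(seq_len(n), train_idx)
    list(train = subset_patch_set(patchset, train_idx),
         test = subset_patch_set(patchset, test_idx))
  })
}

#' Train the patch classifier
#'
#' Minimizes softmax cross-entropy plus a small L2 penalty with Adadelta,
#' monitoring the test-set cost after every epoch and stopping by the
#' patience rule of [early_stop_epoch()] (or at `max_epochs`).
#'
#' @param model an untrained [build_network()] model.
#' @param train_set,test_set `patch_set`s; both classes must be present in
#'   each.
#' @param config a [train_config()].
#' @return The trained model, with a `history` data frame (per-epoch train
#'   and test cross-entropy and accuracy, the test-cost improvement, and
#'   attributes `stopped_epoch` / `stop_reason`).
#' @export
train_network <- function(model, train_set, test_set, config = train_config()) {
  stopifnot(inherits(model, "mparseg_model"))
  for (s in list(train_set, test_set)) {
    if (length(s$labels) == 0L) stopf("empty patch set")
    if (length(unique(s$labels)) < 2L) {
      stopf("both classes must be present in the training and test sets")
    }
  }
  if (dim(train_set$patches)[1] != model$patch_edge) {
    stopf("patch edge of the data (%d) does not match the model (%d)",
          dim(train_set$patches)[1], model$patch_edge)
  }
  params <- model$params
  state <- adadelta_init(params)
  n_train <- length(train_set$labels)
  hist <- list()
  test_costs <- numeric(0)
  stop_reason <- "max_epochs"
  stopped <- config$max_epochs
  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n_train)
      ep_loss <- 0
      ep_hits <- 0
      for (start in seq(1, n_train, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n_train)]
        xb <- train_set$patches[, , , idx, drop = FALSE]
        yb <- train_set$labels[idx]
        fw <- nn_forward(model$spec, params, xb, dropout = TRUE)
        lo <- nn_loss(fw$probs, yb, params, config$l2)
        if (!is.finite(lo$loss)) {
          cond <- structure(
            class = c("mparseg_divergence", "error", "condition"),
            list(message = sprintf("training diverged at epoch %d (non-finite cost)", epoch),
                 call = sys.call(-1),
                 history = do.call(rbind, hist))
          )
          stop(cond)
        }
        grads <- nn_backward(model$spec, params, fw, yb, config$l2)
        upd <- adadelta_update(params, grads, state, config)
        params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + lo$loss * length(idx)
        ep_hits <- ep_hits + sum(lo$pred == yb)
      }
      tr_cost <- ep_loss / n_train
      tr_acc <- ep_hits / n_train
      te <- nn_evaluate(model$spec, params, test_set, config)
      test_costs <- c(test_costs, te$cost)
      improvement <- if (epoch == 1) Inf else
        test_costs[epoch - 1] - test_costs[epoch]
      hist[[epoch]] <- data.frame(
        epoch = epoch, train_cost = tr_cost, train_acc = tr_acc,
        test_cost = te$cost, test_acc = te$acc, improvement = improvement
      )
      if (config$verbose) {
        message(sprintf(
          "epoch %3d  train %.4f/%.3f  test %.4f/%.3f  imp %.2g",
          epoch, tr_cost, tr_acc, te$cost, te$acc, improvement))
      }
      es <- early_stop_epoch(test_costs, config$patience,
                             config$improvement_tol)
      if (!is.na(es)) {
        stop_reason <- "patience"
        stopped <- epoch
        break
      }
      stopped <- epoch
    }
  })
  model$params <- params
  history <- do.call(rbind, hist)
  attr(history, "stopped_epoch") <- stopped
  attr(history, "stop_reason") <- stop_reason
  model$history <- history
  model$train_config <- config
  model
}

# Test-set cost/accuracy in evaluation mode (dropout off), chunked.
nn_evaluate <- function(spec, params, patch_set, config, chunk = 1024L) {
  n <- length(patch_set$labels)
  loss <- 0
  hits <- 0
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    fw <- nn_forward(spec, params,
                     patch_set$patches[, , , idx, drop = FALSE],
                     dropout = FALSE)
    lo <- nn_loss(fw$probs, patch_set$labels[idx], params, config$l2)
    loss <- loss + lo$ce * length(idx)
    hits <- hits + sum(lo$pred == patch_set$labels[idx])
  }
  # report pure cross-entropy on the test set (the monitored cost delta)
  list(cost = loss / n + 0.5 * config$l2 * nn_weight_sq(params),
       acc = hits / n)
}

#' Classify a batch of patches
#'
#' @param model a trained `mparseg_model`.
#' @param patches M x M x 3 x n array (or a single M x M x 3 tile).
#' @param batch internal chunk size.
#' @return n x 2 matrix of class probabilities (columns: background,
#'   tumour); rows sum to one.
#' @export
predict_patches <- function(model, patches, batch = 2048L) {
  if (length(dim(patches)) == 3L) {
    patches <- array(patches, dim = c(dim(patches), 1))
  }
  n <- dim(patches)[4]
  out <- matrix(0, n, 2)
  for (start in seq(1, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    fw <- nn_forward(model$spec, model$params,
                     patches[, , , idx, drop = FALSE], dropout = FALSE)
    out[idx, ] <- t(fw$probs)
  }
  colnames(out) <- c("background", "tumour")
  out
}

#' Save / load a model checkpoint
#'
#' Checkpoints are self-describing JSON: network spec, patch edge, fitted
#' parameters, training configuration and history.
#'
#' @param model a `mparseg_model`.
#' @param path output path (`.json`).
#' @return `path` invisibly (for `save_model`); the restored model (for
#'   `load_model`).
#' @export
save_model <- function(model, path) {
  ser <- list(
    spec = unclass(model$spec),
    patch_edge = model$patch_edge,
    n_channels = model$n_channels,
    params = lapply(model$params, function(p) {
      list(dim = dim(p) %||% length(p), values = as.numeric(p))
    }),
    train_config = if (!is.null(model$train_config)) unclass(model$train_config),
    history = model$history,
    stopped_epoch = attr(model$history, "stopped_epoch"),
    stop_reason = attr(model$history, "stop_reason")
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(network_spec, ser$spec[setdiff(names(ser$spec), NULL)])
  params <- lapply(ser$params, function(p) {
    d <- as.integer(p$dim)
    if (length(d) > 1L) array(p$values, d) else as.numeric(p$values)
  })
  model <- build_network(spec, ser$patch_edge, ser$n_channels, seed = 1L)
  model$params <- params
  if (!is.null(ser$history)) {
    h <- as.data.frame(ser$history)
    attr(h, "stopped_epoch") <- ser$stopped_epoch
    attr(h, "stop_reason") <- ser$stop_reason
    model$history <- h
  }
  model
}

#' Export a training history as a plain-text table
#'
#' @param model a trained model.
#' @param path output path (tab-separated).
#' @export
write_history <- function(model, path) {
  if (is.null(model$history)) stopf("model has no training history")
  write.table(model$history, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
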