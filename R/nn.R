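# Feed-forward classifier: three ReLU hidden layers (256, 128, 64) with
# interleaved dropout (0.40, 0.30, 0.20), a sigmoid output unit, binary
# cross-entropy loss, Glorot-uniform initialisation, minibatch SGD/Adam,
# and early stopping on an internal validation split with best-weight
# restoration. Written directly on base-R matrix algebra; all stochastic
# steps (init, shuffling, dropout, splits) consume explicit seeds.

#' Network architecture configuration
#'
#' @param hidden_sizes integer vector of hidden-layer widths (default
#'   `c(256, 128, 64)`).
#' @param dropout_rates per-hidden-layer dropout probabilities, each in
#'   \[0, 1), non-increasing (default `c(0.40, 0.30, 0.20)`).
#' @param seed seed for Glorot-uniform weight initialisation.
#' @return a `network_config` list.
#' @export
network_config <- function(hidden_sizes = c(256L, 128L, 64L),
                           dropout_rates = c(0.40, 0.30, 0.20),
                           seed = 1L) {
  stopifnot(length(hidden_sizes) == length(dropout_rates),
            all(hidden_sizes >= 1),
            all(dropout_rates >= 0 & dropout_rates < 1),
            !is.unsorted(rev(dropout_rates)))
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 dropout_rates = dropout_rates, seed = as.integer(seed)),
            class = "network_config")
}

#' Training configuration
#'
#' Defaults follow the documented protocol: binary cross-entropy loss,
#' SGD with learning rate 0.001, batch size 32, up to 1000 epochs, and
#' early stopping (patience 20) monitoring the loss on a 10% stratified
#' validation split of the training data, restoring the best weights.
#'
#' @param optimizer `"sgd"` or `"adam"`.
#' @param learning_rate positive step size (grid values: 0.1, 0.01, 0.001).
#' @param batch_size minibatch size (default 32).
#' @param max_epochs epoch budget (default 1000).
#' @param patience early-stopping patience in epochs (default 20).
#' @param validation_fraction fraction of the training data held out for
#'   early-stopping monitoring (default 0.10).
#' @param class_weighted weight the loss inversely to class frequency
#'   (default `FALSE`; evaluated but off by default).
#' @param seed seed for the validation split, shuffling and dropout.
#' @return a `train_config` list.
#' @export
train_config <- function(optimizer = c("sgd", "adam"), learning_rate = 0.001,
                         batch_size = 32L, max_epochs = 1000L, patience = 20L,
                         validation_fraction = 0.10, class_weighted = FALSE,
                         seed = 1L) {
  optimizer <- match.arg(optimizer)
  stopifnot(learning_rate > 0, batch_size >= 1, patience >= 1,
            max_epochs >= 1,
            validation_fraction > 0, validation_fraction < 1)
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 validation_fraction = validation_fraction,
                 class_weighted = isTRUE(class_weighted),
                 seed = as.integer(seed)),
            class = "train_config")
}

# Coerce labels to 0/1 with 1 = case.
as_binary_labels <- function(labels) {
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1",
                                        call. = FALSE)
    return(as.numeric(labels))
  }
  labels <- as.character(labels)
  known <- c(case = 1, control = 0, aux_control = 0)
  if (!all(labels %in% names(known))) {
    stop("labels must be 0/1 or case/control/aux_control", call. = FALSE)
  }
  unname(known[labels])
}

glorot_uniform <- function(fan_in, fan_out) {
  limit <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -limit, limit), fan_in, fan_out)
}

init_params <- function(n_features, net) {
  sizes <- c(n_features, net$hidden_sizes, 1L)
  lapply(seq_len(length(sizes) - 1L), function(l) {
    list(W = glorot_uniform(sizes[l], sizes[l + 1L]),
         b = rep(0, sizes[l + 1L]))
  })
}

# Forward pass; when `dropout` is supplied (list of inverted-dropout
# masks, stored as plain vectors in column-major layout) applies it
# after each hidden ReLU. Written for minimal allocation: the loop runs
# once per minibatch during training.
nn_forward <- function(X, params, dropout = NULL) {
  L <- length(params)
  acts <- vector("list", L)
  acts[[1L]] <- X
  A <- X
  n <- nrow(X)
  for (l in seq_len(L - 1L)) {
    Z <- A %*% params[[l]]$W
    Z <- Z + rep(params[[l]]$b, each = n)
    A <- Z * (Z > 0)
    if (!is.null(dropout)) A <- A * dropout[[l]]
    acts[[l + 1L]] <- A
  }
  z_out <- as.numeric(A %*% params[[L]]$W) + params[[L]]$b
  list(acts = acts, z = z_out, p = sigmoid(z_out))
}

# Numerically stable mean binary cross-entropy from the output logit.
bce_from_logit <- function(z, y, w = NULL) {
  ll <- pmax(z, 0) - y * z + log1p(exp(-abs(z)))
  if (is.null(w)) mean(ll) else sum(w * ll) / sum(w)
}

# One backward pass; returns gradients matching the params structure.
nn_backward <- function(fw, y, params, dropout, w = NULL) {
  L <- length(params)
  n <- length(y)
  wn <- if (is.null(w)) rep(1 / n, n) else w / sum(w)
  delta <- matrix((fw$p - y) * wn, ncol = 1L)   # d loss / d z_out
  grads <- vector("list", L)
  for (l in L:1) {
    A_prev <- fw$acts[[l]]
    grads[[l]] <- list(W = crossprod(A_prev, delta),
                       b = colSums(delta))
    if (l > 1L) {
      dA <- tcrossprod(delta, params[[l]]$W)
      A <- fw$acts[[l]]
      # inverted-dropout scaling reapplied, then ReLU derivative (A <= 0
      # covers both negative pre-activations and dropped units)
      dA <- dA * dropout[[l - 1L]]
      dA[A <= 0] <- 0
      delta <- dA
    }
  }
  grads
}

adam_state <- function(params) {
  lapply(params, function(p) list(mW = p$W * 0, vW = p$W * 0,
                                  mb = p$b * 0, vb = p$b * 0))
}

apply_update <- function(params, grads, train, state, t) {
  lr <- train$learning_rate
  if (train$optimizer == "sgd") {
    for (l in seq_along(params)) {
      params[[l]]$W <- params[[l]]$W - lr * grads[[l]]$W
      params[[l]]$b <- params[[l]]$b - lr * grads[[l]]$b
    }
    return(list(params = params, state = state))
  }
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (l in seq_along(params)) {
    s <- state[[l]]
    s$mW <- b1 * s$mW + (1 - b1) * grads[[l]]$W
    s$vW <- b2 * s$vW + (1 - b2) * grads[[l]]$W^2
    s$mb <- b1 * s$mb + (1 - b1) * grads[[l]]$b
    s$vb <- b2 * s$vb + (1 - b2) * grads[[l]]$b^2
    mW_hat <- s$mW / (1 - b1^t); vW_hat <- s$vW / (1 - b2^t)
    mb_hat <- s$mb / (1 - b1^t); vb_hat <- s$vb / (1 - b2^t)
    params[[l]]$W <- params[[l]]$W - lr * mW_hat / (sqrt(vW_hat) + eps)
    params[[l]]$b <- params[[l]]$b - lr * mb_hat / (sqrt(vb_hat) + eps)
    state[[l]] <- s
  }
  list(params = params, state = state)
}

# Stratified index split: returns indices of the validation part.
stratified_holdout <- function(y, fraction) {
  idx <- unlist(lapply(unique(y), function(cl) {
    pool <- which(y == cl)
    k <- max(1L, round(length(pool) * fraction))
    sample(pool, min(k, length(pool)))
  }))
  sort(idx)
}

#' Fit the feed-forward classifier
#'
#' Trains the network on a feature matrix and binary labels. A stratified
#' `validation_fraction` of the rows is held out internally; training
#' stops when its loss has not improved for `patience` epochs (or at
#' `max_epochs`) and the best-epoch weights are restored. Deterministic
#' given the configuration seeds.
#'
#' @param features numeric matrix (subjects x features), no missing values.
#' @param labels 0/1 vector or case/control labels (1 = case).
#' @param net a [network_config()].
#' @param train a [train_config()].
#' @return a `risk_model` with elements `params`, `net`, `train`,
#'   `n_features`, `history` (per-epoch train/validation loss) and
#'   `best_epoch`.
#' @export
fit_network <- function(features, labels, net = network_config(),
                        train = train_config()) {
  X <- as.matrix(unclass(features))
  if (anyNA(X)) stop("features contain missing values", call. = FALSE)
  y <- as_binary_labels(labels)
  stopifnot(length(y) == nrow(X))
  if (length(unique(y)) < 2) {
    stop("both classes must be present to fit the classifier", call. = FALSE)
  }

  combined_seed <- (as.numeric(net$seed) * 1000003 + as.numeric(train$seed)) %%
    2147483647
  with_seed(combined_seed, {
    params <- init_params(ncol(X), net)
    val_idx <- stratified_holdout(y, train$validation_fraction)
    tr_idx <- setdiff(seq_len(nrow(X)), val_idx)
    Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
    Xva <- X[val_idx, , drop = FALSE]; yva <- y[val_idx]

    w <- NULL
    if (train$class_weighted) {
      tab <- table(factor(ytr, levels = c(0, 1)))
      w <- length(ytr) / (2 * as.numeric(tab[as.character(ytr)]))
    }

    state <- if (train$optimizer == "adam") adam_state(params) else NULL
    best <- list(loss = Inf, params = params, epoch = 0L)
    tr_losses <- va_losses <- numeric(train$max_epochs)
    keep_prob <- 1 - net$dropout_rates
    sizes <- net$hidden_sizes
    n_hidden <- length(sizes)
    stall <- 0L; t <- 0L; epochs_run <- 0L
    n_tr <- nrow(Xtr)

    for (epoch in seq_len(train$max_epochs)) {
      ord <- sample.int(n_tr)
      starts <- seq(1L, n_tr, by = train$batch_size)
      loss_sum <- 0; loss_n <- 0L
      for (s in starts) {
        rows <- ord[s:min(s + train$batch_size - 1L, n_tr)]
        nb <- length(rows)
        Xb <- Xtr[rows, , drop = FALSE]
        # one bulk uniform draw per batch, sliced into the per-layer
        # inverted-dropout masks
        u <- stats::runif(nb * sum(sizes))
        masks <- vector("list", n_hidden)
        off <- 0L
        for (l in seq_len(n_hidden)) {
          len <- nb * sizes[l]
          masks[[l]] <- if (net$dropout_rates[l] == 0) {
            1
          } else {
            (u[(off + 1L):(off + len)] < keep_prob[l]) / keep_prob[l]
          }
          off <- off + len
        }
        fw <- nn_forward(Xb, params, dropout = masks)
        if (any(!is.finite(fw$z))) {
          stop(sprintf(
            "non-finite loss at epoch %d (learning rate %g); reduce the rate",
            epoch, train$learning_rate), call. = FALSE)
        }
        yb <- ytr[rows]
        wb <- if (is.null(w)) NULL else w[rows]
        loss_sum <- loss_sum + nb * bce_from_logit(fw$z, yb, wb)
        loss_n <- loss_n + nb
        grads <- nn_backward(fw, yb, params, masks, w = wb)
        t <- t + 1L
        upd <- apply_update(params, grads, train, state, t)
        params <- upd$params; state <- upd$state
      }
      va_loss <- bce_from_logit(nn_forward(Xva, params)$z, yva)
      epochs_run <- epoch
      tr_losses[epoch] <- loss_sum / loss_n  # mean of minibatch losses
      va_losses[epoch] <- va_loss
      if (va_loss < best$loss - 1e-9) {
        best <- list(loss = va_loss, params = params, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= train$patience) break
      }
    }

    history <- data.frame(epoch = seq_len(epochs_run),
                          train_loss = tr_losses[seq_len(epochs_run)],
                          val_loss = va_losses[seq_len(epochs_run)])
    structure(list(params = best$params, net = net, train = train,
                   n_features = ncol(X), best_epoch = best$epoch,
                   history = history),
              class = "risk_model")
  })
}

#' Predict case probabilities
#'
#' @param model a fitted `risk_model` from [fit_network()].
#' @param features numeric matrix with the training feature width.
#' @return per-subject probabilities in (0, 1), in row order.
#' @export
predict_proba <- function(model, features) {
  X <- as.matrix(unclass(features))
  if (ncol(X) != model$n_features) {
    stop(sprintf("feature width %d does not match training width %d",
                 ncol(X), model$n_features), call. = FALSE)
  }
  if (anyNA(X)) stop("features contain missing values", call. = FALSE)
  nn_forward(X, model$params)$p
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf(
    "<risk_model> %d features -> [%s] -> 1; %s lr=%g; best epoch %d\n",
    x$n_features, paste(x$net$hidden_sizes, collapse = ", "),
    x$train$optimizer, x$train$learning_rate, x$best_epoch))
  invisible(x)
}

#' Serialise / restore a fitted model
#'
#' Writes weights and configuration as a single portable JSON file.
#'
#' @param model a `risk_model`.
#' @param path output JSON path.
#' @return `save_model` returns `path` invisibly; `load_model` a
#'   `risk_model`.
#' @export
save_model <- function(model, path) {
  obj <- list(
    net = unclass(model$net), train = unclass(model$train),
    n_features = model$n_features, best_epoch = model$best_epoch,
    layers = lapply(model$params, function(p) {
      list(W = unname(as.matrix(p$W)), b = unname(p$b))
    }))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(seq_len(nrow(obj$layers)), function(l) {
    list(W = as.matrix(obj$layers$W[[l]]), b = as.numeric(obj$layers$b[[l]]))
  })
  structure(list(params = params,
                 net = do.call(network_config, obj$net[c("hidden_sizes",
                                                         "dropout_rates",
                                                         "seed")]),
                 train = do.call(train_config, obj$train),
                 n_features = obj$n_features, best_epoch = obj$best_epoch,
                 history = NULL),
            class = "risk_model")
}
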