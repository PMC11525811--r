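# Loss, sparse backpropagation through time, optimizer steps, and the two
# pruning operations (probabilistic connection deletion and redundant-
# neuron removal).

#' Mean-squared-error sequence loss
#'
#' `J = (1/I_T) sum_t (Yhat^t - Y^t)' (Yhat^t - Y^t)`, averaged over the
#' sample columns when the steps carry batches.
#'
#' @param yhat,y lists of `N_O x B` matrices (or vectors), equal lengths.
#' @return scalar loss.
#' @export
loss_mse <- function(yhat, y) {
  if (!is.list(yhat)) yhat <- list(yhat)
  if (!is.list(y)) y <- list(y)
  if (length(yhat) != length(y)) stop("loss_mse: sequence lengths differ")
  terms <- mapply(function(a, b) {
    a <- as.matrix(a); b <- as.matrix(b)
    if (!all(dim(a) == dim(b))) stop("loss_mse: shape mismatch")
    sum((a - b)^2) / ncol(a)
  }, yhat, y)
  sum(terms) / length(yhat)
}

#' Sparse backpropagation through time
#'
#' Reverse-mode differentiation of the forward recursion
#' `S^(t+1) = f_UAF(W Q^t + H)` under the MSE sequence loss. Gradients are
#' accumulated only at the live sparse positions of `W` (row-major entry
#' order), and the per-step overwrite of the input slots of `Q` cuts
#' gradient flow into the overwritten coordinates. Bias and activation
#' parameters accumulate through the same chain via [uaf_gradients()].
#'
#' @param model a `raynn_model`.
#' @param inputs forward input sequence (see [forward()]).
#' @param targets list of target matrices, one per input step.
#' @param k propagation delay; defaults to the model's.
#' @param fwd optional pre-computed `forward(..., record = TRUE)` result.
#' @return list with `dW` (length `nnz`, aligned with the row-major entry
#'   order of `model$W`), `dH` (length `N`), `dC` (`N x 5`), and the
#'   realized `loss`.
#' @export
backprop <- function(model, inputs, targets, k = model$k, fwd = NULL) {
  if (is.null(fwd)) fwd <- forward(model, inputs, k = k, record = TRUE)
  if (is.null(fwd$Q)) stop("backprop: forward history missing (record = TRUE)")
  Xs <- .as_input_list(inputs, model$N_I)
  Ys <- .as_input_list(targets, model$N_O)
  I_T <- fwd$I_T; B <- fwd$B; U <- I_T + k
  N <- model$N
  outs <- seq.int(N - model$N_O + 1L, length.out = model$N_O)
  Wt <- Matrix::t(.sw_matrix(model$W))
  ei <- model$W$i; ej <- model$W$j
  dW <- numeric(nnz(model$W))
  dH <- numeric(N)
  dC <- matrix(0, N, 5L)
  dS <- matrix(0, N, B)
  loss <- loss_mse(fwd$outputs, Ys)
  for (ts in seq.int(U - 1L, 1L)) {        # state step index of S^(ts)
    t_in <- ts - k                          # input step whose output is S^(ts)
    if (t_in >= 0L && t_in <= I_T - 1L) {
      E <- fwd$outputs[[t_in + 1L]] - Ys[[t_in + 1L]]
      dS[outs, ] <- dS[outs, , drop = FALSE] + (2 / (I_T * B)) * E
    }
    Z <- fwd$Z[[ts]]                        # S^(ts) = f(Z^(ts-1))
    Q <- fwd$Q[[ts]]
    g <- .uaf_grad_mat(Z, model$C_eff)
    gx <- dS * g$dx
    dH <- dH + rowSums(gx)
    dC[, 1L] <- dC[, 1L] + rowSums(dS * g$dA)
    dC[, 2L] <- dC[, 2L] + rowSums(dS * g$dB)
    dC[, 3L] <- dC[, 3L] + rowSums(dS * g$dC)
    dC[, 4L] <- dC[, 4L] + rowSums(dS * g$dD)
    dC[, 5L] <- dC[, 5L] + rowSums(dS * g$dE)
    if (length(dW))
      dW <- dW + rowSums(gx[ei, , drop = FALSE] * Q[ej, , drop = FALSE])
    dS <- as.matrix(Wt %*% gx)
    if (model$N_I > 0L) dS[seq_len(model$N_I), ] <- 0  # Q overwrite cuts flow
  }
  list(dW = dW, dH = dH, dC = dC, loss = loss)
}

#' Training configuration
#'
#' @param optimizer `"adam"` (default: beta1 0.9, beta2 0.999, eps 1e-8)
#'   or `"sgd"`.
#' @param lr learning rate (> 0).
#' @param epochs training epochs.
#' @param delete_fraction fraction of live weights removed per pruning
#'   sweep (default 0.05).
#' @param prune_every epochs between pruning sweeps (0 disables pruning).
#' @param prune_neurons also remove redundant neurons after each sweep.
#' @param seed integer seed.
#' @return a `train_config` list.
#' @export
train_config <- function(optimizer = c("adam", "sgd"), lr = 0.01,
                         epochs = 100L, delete_fraction = 0.05,
                         prune_every = 0L, prune_neurons = TRUE, seed = 1L) {
  optimizer <- match.arg(optimizer)
  stopifnot(lr > 0, delete_fraction >= 0, delete_fraction < 1)
  structure(list(optimizer = optimizer, lr = lr, epochs = as.integer(epochs),
                 delete_fraction = delete_fraction,
                 prune_every = as.integer(prune_every),
                 prune_neurons = isTRUE(prune_neurons),
                 beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                 seed = as.integer(seed)),
            class = "train_config")
}

# mask of slots whose bias / activation rows are trainable
.trainable_slots <- function(model) {
  model$slot_active & seq_len(model$N) > model$N_I
}

#' Apply one optimizer update
#'
#' Updates the live weight values, the biases of active non-input slots,
#' and the activation parameters with SGD or Adam. Structural zeros are
#' never touched; Adam moment vectors live in `model$opt_state` and are
#' reset whenever the entry layout changes.
#'
#' @param model a `raynn_model`.
#' @param grads gradients from [backprop()].
#' @param config a [train_config()].
#' @return the updated model.
#' @export
optimizer_step <- function(model, grads, config) {
  mask <- .trainable_slots(model)
  gH <- grads$dH * mask
  gC <- grads$dC * mask
  theta <- c(grads$dW, gH, as.numeric(gC))
  if (config$optimizer == "sgd") {
    delta <- config$lr * theta
  } else {
    st <- model$opt_state
    if (is.null(st) || length(st$m) != length(theta))
      st <- list(m = numeric(length(theta)), v = numeric(length(theta)), t = 0L)
    st$t <- st$t + 1L
    st$m <- config$beta1 * st$m + (1 - config$beta1) * theta
    st$v <- config$beta2 * st$v + (1 - config$beta2) * theta^2
    mhat <- st$m / (1 - config$beta1^st$t)
    vhat <- st$v / (1 - config$beta2^st$t)
    delta <- config$lr * mhat / (sqrt(vhat) + config$eps)
    model$opt_state <- st
  }
  nw <- nnz(model$W)
  N <- model$N
  if (nw) model$W$x <- model$W$x - delta[seq_len(nw)]
  model$H <- model$H - delta[nw + seq_len(N)]
  model$C_eff <- model$C_eff - matrix(delta[nw + N + seq_len(5L * N)], N, 5L)
  model
}

#' Probabilistic deletion of the smallest-scoring connections
#'
#' Each live entry receives a score `R * w` with `R ~ Uniform(0, 1)`; the
#' `ceiling(fraction * nnz)` entries with smallest `|score|` are removed
#' (stable tie-break by entry order). Zero-valued weights score exactly 0
#' and are always removed first; larger weights are removed with ever
#' lower probability.
#'
#' @param W a [sparse_weights()].
#' @param fraction fraction of live entries to remove, in `[0, 1)`.
#' @param seed integer seed.
#' @return list with `W` (pruned) and `deleted` (data.frame i, j, x of the
#'   removed entries in removal order).
#' @export
delete_connections_probabilistic <- function(W, fraction = 0.05, seed = 1L) {
  stopifnot(fraction >= 0, fraction < 1)
  n <- nnz(W)
  n_del <- ceiling(fraction * n)
  if (n == 0L || n_del == 0L)
    return(list(W = W, deleted = data.frame(i = integer(0), j = integer(0),
                                            x = numeric(0))))
  set.seed(seed)
  score <- abs(runif(n) * W$x)
  ord <- order(score, seq_len(n))          # stable: ties by entry order
  del <- sort(ord[seq_len(n_del)])
  keep <- setdiff(seq_len(n), del)
  list(W = sparse_weights(W$i[keep], W$j[keep], W$x[keep], W$N),
       deleted = data.frame(i = W$i[del], j = W$j[del], x = W$x[del]))
}

#' Remove neurons whose outputs were all deleted
#'
#' A non-output neuron with out-degree zero (no live entry in its column)
#' cannot influence any other neuron: its incoming row is zeroed, its bias
#' and activation row reset, and its position is removed from the
#' population. The sweep repeats to a fixed point so chains of dead-ended
#' neurons cascade. Only hidden neurons are eligible — removing an input
#' slot would change the model's input dimension, so disconnected inputs
#' are left in place (and reported by [verify_io_connectivity()]).
#' Forward outputs on any input sequence are bitwise unchanged.
#'
#' @param model a `raynn_model`.
#' @return list with `model` and `removed` (slot indices, removal order).
#' @export
delete_redundant_neurons <- function(model) {
  removed <- integer(0)
  repeat {
    outdeg <- tabulate(model$W$j, nbins = model$N)
    hidden <- which(model$slot_active &
                      seq_len(model$N) > model$N_I &
                      seq_len(model$N) <= model$N - model$N_O)
    dead <- hidden[outdeg[hidden] == 0L]
    if (!length(dead)) break
    keep <- !(model$W$i %in% dead)
    model$W <- sparse_weights(model$W$i[keep], model$W$j[keep],
                              model$W$x[keep], model$W$N)
    for (s in dead) {
      p <- model$slot_pop[s]
      model$population$positions <- model$population$positions[-p, , drop = FALSE]
      model$population$cell_type <- model$population$cell_type[-p]
      shift <- !is.na(model$slot_pop) & model$slot_pop > p
      model$slot_pop[shift] <- model$slot_pop[shift] - 1L
      model$slot_pop[s] <- NA_integer_
      model$slot_active[s] <- FALSE
      model$H[s] <- 0
      model$C_eff[s, ] <- c(1, 0, 0, -1, 0)
    }
    model$opt_state <- NULL
    removed <- c(removed, dead)
  }
  list(model = model, removed = removed)
}

#' Count trainable parameters
#'
#' Live weights, plus one bias and five activation parameters per active
#' non-input neuron slot.
#'
#' @param model a `raynn_model`.
#' @return integer count.
#' @export
count_trainable_params <- function(model) {
  n_cn <- sum(.trainable_slots(model))
  nnz(model$W) + n_cn + 5L * n_cn
}

#' Train a model on an input/target sequence set
#'
#' Full-batch gradient training: each epoch runs one forward/backward pass
#' over the whole batch and one optimizer update. When pruning is enabled,
#' every `prune_every` epochs a probabilistic deletion sweep removes
#' `delete_fraction` of the live weights, followed (optionally) by
#' redundant-neuron removal; the optimizer state is reset because the
#' entry layout changed.
#'
#' @param model a `raynn_model`.
#' @param inputs,targets forward input and target sequences (see
#'   [forward()]); columns are samples trained in full batch.
#' @param config a [train_config()].
#' @param val optional list(inputs, targets) evaluated each epoch.
#' @param loss_target optional early-stop threshold on the training loss;
#'   recorded as `epochs_to_target` (NA when never reached).
#' @param stop_at_target stop training once `loss_target` is reached.
#' @return list with `model`, `log` (data.frame per epoch), and
#'   `epochs_to_target`.
#' @export
train_model <- function(model, inputs, targets, config = train_config(),
                        val = NULL, loss_target = NULL,
                        stop_at_target = FALSE) {
  log <- vector("list", config$epochs)
  epochs_to_target <- NA_integer_
  for (ep in seq_len(config$epochs)) {
    gr <- backprop(model, inputs, targets)
    model <- optimizer_step(model, gr, config)
    J_val <- NA_real_
    if (!is.null(val)) {
      fv <- forward(model, val$inputs)
      J_val <- loss_mse(fv$outputs, .as_input_list(val$targets, model$N_O))
    }
    if (config$prune_every > 0L && ep %% config$prune_every == 0L) {
      pr <- delete_connections_probabilistic(
        model$W, config$delete_fraction,
        seed = derive_seed(config$seed, paste0("prune", ep)))
      model$W <- pr$W
      model$opt_state <- NULL
      if (config$prune_neurons) model <- delete_redundant_neurons(model)$model
    }
    log[[ep]] <- data.frame(epoch = ep, J_train = gr$loss, J_val = J_val,
                            nnz = nnz(model$W),
                            active_neurons = sum(model$slot_active),
                            params = count_trainable_params(model))
    if (!is.null(loss_target) && is.na(epochs_to_target) &&
        gr$loss <= loss_target) {
      epochs_to_target <- ep
      if (stop_at_target) { log <- log[seq_len(ep)]; break }
    }
  }
  list(model = model, log = do.call(rbind, log),
       epochs_to_target = epochs_to_target)
}
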