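# Sparse weighted adjacency matrix and the time-stepped forward pass.
#
# Entry (i, j) of W carries the signal FROM neuron j INTO neuron i under
# the product W Q (so a ray-traced connection source -> target lands at
# row = target slot, col = source slot). Entries are kept in coordinate
# form sorted row-major — the flattening order of the gradient vector —
# and converted to a compressed-sparse column product form on demand.

#' Construct a sparse weight container
#'
#' @param i,j 1-based row (into) and column (from) slot indices.
#' @param x weight values.
#' @param N capacity: total neuron slots (must exceed the active count).
#' @return a `sparse_weights` list with entries sorted row-major.
#' @export
sparse_weights <- function(i = integer(0), j = integer(0), x = numeric(0), N) {
  stopifnot(length(i) == length(j), length(j) == length(x))
  if (length(i) && (max(i) > N || max(j) > N || min(i) < 1L || min(j) < 1L))
    stop("sparse_weights: indices out of 1..N")
  if (anyDuplicated(paste(i, j)))
    stop("sparse_weights: duplicate (i, j) entries; deduplicate upstream")
  ord <- order(i, j)
  structure(list(N = as.integer(N), i = as.integer(i)[ord],
                 j = as.integer(j)[ord], x = as.numeric(x)[ord]),
            class = "sparse_weights")
}

#' Number of live entries
#' @param W a `sparse_weights`.
#' @export
nnz <- function(W) length(W$x)

#' @export
print.sparse_weights <- function(x, ...) {
  cat(sprintf("<sparse_weights> %d x %d, %d live entries\n", x$N, x$N, nnz(x)))
  invisible(x)
}

# product form (dgCMatrix)
.sw_matrix <- function(W) {
  Matrix::sparseMatrix(i = W$i, j = W$j, x = W$x, dims = c(W$N, W$N))
}

#' Enforce the structural-zero pattern of the adjacency matrix
#'
#' Removes every entry in the first `N_I` rows (nothing may feed into an
#' input slot), in the last `N_O` columns (nothing may leave an output
#' slot), and on the diagonal unless self-loops are allowed.
#'
#' @param W a [sparse_weights()].
#' @param N_I,N_O input and output slot counts.
#' @param allow_self_loops keep diagonal entries when `TRUE`.
#' @return the filtered `sparse_weights`.
#' @export
enforce_structural_zeros <- function(W, N_I, N_O, allow_self_loops = FALSE) {
  keep <- W$i > N_I & W$j <= W$N - N_O
  if (!allow_self_loops) keep <- keep & W$i != W$j
  sparse_weights(W$i[keep], W$j[keep], W$x[keep], W$N)
}

#' Xavier-uniform initialization of connection weights
#'
#' Creates one entry per connection at (row = target slot, col = source
#' slot) with weights drawn Uniform(-b, b), `b = sqrt(6 / (fan_in +
#' fan_out))`, where `fan_in` is the number of entries in the row and
#' `fan_out` the number in the column. Structural zeroing is applied
#' afterwards by the caller.
#'
#' @param rows,cols 1-based target-row and source-column slot indices per
#'   connection (no duplicates).
#' @param N slot capacity.
#' @param seed integer seed.
#' @return a [sparse_weights()].
#' @export
init_weights_xavier <- function(rows, cols, N, seed = 1L) {
  if (anyDuplicated(paste(rows, cols)))
    stop("init_weights_xavier: duplicate connections; deduplicate upstream")
  n <- length(rows)
  if (n == 0L) return(sparse_weights(N = N))
  fan_in <- tabulate(rows, nbins = N)[rows]
  fan_out <- tabulate(cols, nbins = N)[cols]
  bound <- sqrt(6 / (fan_in + fan_out))
  set.seed(seed)
  w <- runif(n, -1, 1) * bound
  sparse_weights(rows, cols, w, N)
}

# default slot capacity: headroom above the active neuron count
.default_capacity <- function(n_active) {
  max(2L^ceiling(log2(max(1, 1.2 * n_active))), n_active + 1L)
}

#' Assemble a network model from a population and its connections
#'
#' Binds the geometry to the learnable network. Neuron slots are laid out
#' with inputs at 1..N_I, hidden following, and outputs occupying the last
#' `N_O` of the `N` capacity slots; glial cells occupy no slot. Weights
#' are Xavier-initialized from the ray-traced connections and structurally
#' zeroed; biases start at small normal values (zero for input slots) and
#' every activation row starts at the identity plus Gaussian jitter, so an
#' untrained network is near-linear.
#'
#' @param population a [cell_population()] (order: input, hidden, output,
#'   glial).
#' @param conn a [connection_set()] over neuron indices of `population`.
#' @param k propagation delay in time steps; `NULL` chooses the smallest
#'   integer at or above the mean shortest-path length from inputs to
#'   outputs in the traced graph (1 when no path exists).
#' @param N slot capacity; defaults to the next power of two above 1.2x
#'   the active neuron count.
#' @param seed integer seed.
#' @param uaf_jitter standard deviation of the activation-parameter jitter.
#' @param bias_sd standard deviation of the initial biases.
#' @param allow_self_loops keep diagonal weights (default FALSE).
#' @param r_RT cluster radius used to trace `conn` (bookkeeping; reused by
#'   default when the network grows).
#' @return a `raynn_model` list.
#' @export
build_model <- function(population, conn, k = NULL, N = NULL, seed = 1L,
                        uaf_jitter = 0.01, bias_sd = 0.01,
                        allow_self_loops = FALSE, r_RT = NULL) {
  cnt <- population_counts(population)
  N_I <- cnt[["N_I"]]; N_h <- cnt[["N_h"]]; N_O <- cnt[["N_O"]]
  n_neurons <- N_I + N_h + N_O
  if (is.null(N)) N <- .default_capacity(n_neurons)
  if (N <= n_neurons) stop("build_model: capacity N must exceed the active neuron count")
  # neuron index (population order) -> slot
  slot_of <- c(seq_len(N_I + N_h), seq.int(N - N_O + 1L, length.out = N_O))
  conn <- dedup_connections(conn)
  W <- init_weights_xavier(rows = slot_of[conn$target],
                           cols = slot_of[conn$source],
                           N = N, seed = derive_seed(seed, "xavier"))
  W <- enforce_structural_zeros(W, N_I, N_O, allow_self_loops)
  slot_active <- logical(N)
  slot_active[slot_of] <- TRUE
  slot_pop <- rep(NA_integer_, N)
  slot_pop[slot_of] <- seq_len(n_neurons)  # population rows (neurons first)
  set.seed(derive_seed(seed, "bias"))
  H <- numeric(N)
  trainable <- slot_active & seq_len(N) > N_I
  H[trainable] <- rnorm(sum(trainable), 0, bias_sd)
  C_eff <- uaf_identity_params(N)
  set.seed(derive_seed(seed, "uaf"))
  C_eff[trainable, ] <- C_eff[trainable, , drop = FALSE] +
    matrix(rnorm(5 * sum(trainable), 0, uaf_jitter), sum(trainable), 5L)
  model <- structure(list(population = population, N = as.integer(N),
                          N_I = N_I, N_O = N_O, W = W, H = H, C_eff = C_eff,
                          slot_active = slot_active, slot_pop = slot_pop,
                          k = 1L, lambda = 0L, seed = as.integer(seed),
                          r_RT = r_RT, allow_self_loops = allow_self_loops),
                     class = "raynn_model")
  model$k <- if (is.null(k)) default_delay(model) else as.integer(k)
  stopifnot(model$k >= 1L)
  model
}

#' @export
print.raynn_model <- function(x, ...) {
  cat(sprintf("<raynn_model> N = %d slots, %d active neurons (%d in / %d out), nnz = %d, k = %d\n",
              x$N, sum(x$slot_active), x$N_I, x$N_O, nnz(x$W), x$k))
  invisible(x)
}

#' Default propagation delay from graph depth
#'
#' The smallest integer at or above the mean shortest-path length from
#' input slots to output slots over the directed connection graph.
#'
#' @param model a `raynn_model`.
#' @return integer delay `>= 1`.
#' @export
default_delay <- function(model) {
  if (nnz(model$W) == 0L || model$N_I == 0L || model$N_O == 0L) return(1L)
  g <- igraph::graph_from_data_frame(
    data.frame(from = model$W$j, to = model$W$i),
    directed = TRUE, vertices = data.frame(name = seq_len(model$N)))
  outs <- seq.int(model$N - model$N_O + 1L, model$N)
  d <- igraph::distances(g, v = seq_len(model$N_I), to = outs, mode = "out")
  d <- d[is.finite(d)]
  if (!length(d)) return(1L)
  max(1L, as.integer(ceiling(mean(d))))
}

# normalize the inputs argument to a list of N_I x B matrices
.as_input_list <- function(inputs, N_I) {
  if (!is.list(inputs)) inputs <- list(inputs)
  lapply(inputs, function(X) {
    if (is.null(dim(X))) X <- matrix(X, ncol = 1L)
    if (nrow(X) != N_I) stop("forward: input rows must equal N_I")
    X
  })
}

#' Run the time-stepped forward pass
#'
#' Starting from the all-zero state `S^0`, each step copies the state into
#' a temporary vector `Q^t`, overwrites the input slots with the input
#' vector of step `t` (after the last input, the input slots hold the last
#' injected values, or zeros with `flush = "zero"`), and updates
#' `S^(t+1) = f_UAF(W Q^t + H)`. The output of input step `t` is read from
#' the output slots of `S^(t+k)` after `U = I_T + k` total states.
#'
#' @param model a `raynn_model`.
#' @param inputs list of per-step inputs, each a length-`N_I` vector or an
#'   `N_I x B` matrix of samples (columns evolve independently).
#' @param k propagation delay; defaults to the model's.
#' @param flush what the input slots hold during the final `k` steps.
#' @param record keep per-step temporaries for backpropagation.
#' @return list with `outputs` (list of `N_O x B` matrices, one per input
#'   step), `states` (`S^0 .. S^(U-1)`), and when recorded `Q` and `Z`
#'   histories.
#' @export
forward <- function(model, inputs, k = model$k, flush = c("hold", "zero"),
                    record = FALSE) {
  flush <- match.arg(flush)
  stopifnot(k >= 1)
  Xs <- .as_input_list(inputs, model$N_I)
  I_T <- length(Xs)
  B <- ncol(Xs[[1L]])
  U <- I_T + k
  N <- model$N
  Wm <- .sw_matrix(model$W)
  S <- matrix(0, N, B)
  S_list <- vector("list", U); S_list[[1L]] <- S
  Q_list <- if (record) vector("list", U - 1L) else NULL
  Z_list <- if (record) vector("list", U - 1L) else NULL
  for (t0 in seq_len(U - 1L)) {      # t0 = t + 1, t = 0 .. U-2
    t <- t0 - 1L
    Q <- S
    if (model$N_I > 0L) {
      if (t < I_T) Q[seq_len(model$N_I), ] <- Xs[[t0]]
      else Q[seq_len(model$N_I), ] <- if (flush == "hold") Xs[[I_T]] else 0
    }
    Z <- as.matrix(Wm %*% Q) + model$H
    S <- uaf_vector(Z, model$C_eff)
    S_list[[t0 + 1L]] <- S
    if (record) { Q_list[[t0]] <- Q; Z_list[[t0]] <- Z }
  }
  outs <- seq.int(N - model$N_O + 1L, length.out = model$N_O)
  outputs <- lapply(seq_len(I_T), function(t0) {
    S_list[[t0 + k]][outs, , drop = FALSE]   # S^(t + k), t = t0 - 1
  })
  list(outputs = outputs, states = S_list, Q = Q_list, Z = Z_list,
       I_T = I_T, k = k, B = B)
}
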