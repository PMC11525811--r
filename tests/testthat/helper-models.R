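# Shared fixtures, built in code.

# The 4-neuron worked example: W as a dense matrix, identity activations,
# zero bias, 2 inputs / 2 outputs, delay 1.
worked_example_W <- function() {
  matrix(c(0.2, 1.5, -0.1, 0.9,
           -0.8, 0.0, 0.6, -1.0,
           1.0, -0.7, 3.2, 1.2,
           -2.0, -0.5, 0.7, 0.1), 4, 4, byrow = TRUE)
}

# Assemble a model directly from a dense weight matrix (no geometry):
# slots are 1..N with inputs first and outputs last, all active.
make_model_raw <- function(W_dense, N_I, N_O, k = 1L, H = NULL,
                           C_eff = NULL) {
  N <- nrow(W_dense)
  idx <- which(W_dense != 0, arr.ind = TRUE)
  W <- sparse_weights(idx[, 1L], idx[, 2L], W_dense[idx], N)
  type <- c(rep("input", N_I), rep("hidden", N - N_I - N_O),
            rep("output", N_O))
  pop <- cell_population(matrix(0, N, 3), type, r_s = 1)
  structure(list(population = pop, N = N, N_I = N_I, N_O = N_O, W = W,
                 H = H %||% numeric(N),
                 C_eff = C_eff %||% uaf_identity_params(N),
                 slot_active = rep(TRUE, N), slot_pop = seq_len(N),
                 k = as.integer(k), lambda = 0L, seed = 1L, r_RT = NULL,
                 allow_self_loops = TRUE),
            class = "raynn_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A random small recurrent model with arbitrary activation parameters,
# honouring the structural-zero pattern.
rand_small_model <- function(seed, N = 10L, N_I = 2L, N_O = 2L, k = 2L,
                             p_edge = 0.35, param_sd = 0.3,
                             zero_C_rows = integer(0)) {
  set.seed(seed)
  Wd <- matrix(0, N, N)
  for (r in (N_I + 1L):N) for (cl in seq_len(N - N_O))
    if (r != cl && runif(1) < p_edge) Wd[r, cl] <- rnorm(1, 0, 0.5)
  H <- c(numeric(N_I), rnorm(N - N_I, 0, 0.3))
  C_eff <- uaf_identity_params(N) + matrix(rnorm(5 * N, 0, param_sd), N, 5)
  C_eff[zero_C_rows, 3L] <- 0
  make_model_raw(Wd, N_I, N_O, k = k, H = H, C_eff = C_eff)
}

# Numeric loss of a model on fixed sequences (for finite differences).
model_loss <- function(model, X, Y) {
  fv <- forward(model, X)
  loss_mse(fv$outputs, Y)
}

# A random mixed population of hidden and glial cells in a box or ball.
rand_population <- function(seed, n, extent = 10, p_glial = 0.4,
                            ball = FALSE) {
  set.seed(seed)
  if (ball) {
    P <- sample_hidden_positions(n, extent)
  } else {
    P <- matrix(runif(3 * n, -extent, extent), n, 3)
  }
  type <- sample(c("hidden", "glial"), n, replace = TRUE,
                 prob = c(1 - p_glial, p_glial))
  cell_population(P, type, r_s = extent * 2)
}

# Independent double-loop collision oracle (O(M^2), scalar arithmetic).
collision_oracle <- function(P, r_n = 1) {
  M <- nrow(P)
  hit <- logical(M)
  for (a in seq_len(M - 1L)) for (b in (a + 1L):M) {
    dx <- P[a, 1] - P[b, 1]; dy <- P[a, 2] - P[b, 2]; dz <- P[a, 3] - P[b, 3]
    if (sqrt(dx * dx + dy * dy + dz * dz) <= 2 * r_n) hit[a] <- hit[b] <- TRUE
  }
  which(hit)
}

# Independent occlusion oracle via clamped point-to-segment projection.
occlusion_oracle <- function(p_i, p_j, obstacles, r_n = 1) {
  d <- p_j - p_i
  L2 <- sum(d * d)
  for (a in seq_len(nrow(obstacles))) {
    v <- obstacles[a, ] - p_i
    tproj <- sum(v * d) / L2
    if (tproj > 0 && tproj < 1) {
      foot <- p_i + tproj * d
      if (sqrt(sum((obstacles[a, ] - foot)^2)) <= r_n) return(TRUE)
    }
  }
  FALSE
}

edge_keys <- function(conn) sort(paste(conn$source, conn$target))
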