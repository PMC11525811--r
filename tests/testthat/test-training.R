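# Loss, backpropagation through time, optimizer updates, probabilistic
# connection deletion, and redundant-neuron removal.

test_that("MSE sequence loss matches an elementwise loop", {
  expect_equal(loss_mse(list(c(1, 2)), list(c(1, 2))), 0)
  expect_equal(loss_mse(list(c(1, -1)), list(c(0, 0))), 2)
  set.seed(2)
  yh <- list(matrix(rnorm(6), 2), matrix(rnorm(6), 2))
  yy <- list(matrix(rnorm(6), 2), matrix(rnorm(6), 2))
  want <- 0
  for (t in 1:2) for (b in 1:3)
    want <- want + sum((yh[[t]][, b] - yy[[t]][, b])^2) / 3
  expect_equal(loss_mse(yh, yy), want / 2, tolerance = 1e-12)
  expect_error(loss_mse(list(c(1, 2)), list(c(1, 2, 3))), "shape")
})

test_that("backprop reproduces the hand-derived worked example", {
  m <- make_model_raw(worked_example_W(), N_I = 2L, N_O = 2L, k = 1L)
  f <- forward(m, list(c(-2.1, 0.3)))
  # target equal to the prediction: every gradient vanishes
  g0 <- backprop(m, list(c(-2.1, 0.3)), list(as.numeric(f$outputs[[1]])))
  expect_equal(g0$dW, numeric(nnz(m$W)))
  expect_equal(g0$dH, numeric(4))
  expect_equal(max(abs(g0$dC)), 0)
  # target [0, 0]: dJ/dw(3,1) = 2 * (-2.31) * (-2.1) = 9.702
  g <- backprop(m, list(c(-2.1, 0.3)), list(c(0, 0)))
  e31 <- which(m$W$i == 3 & m$W$j == 1)
  expect_equal(g$dW[e31], 2 * (-2.31) * (-2.1), tolerance = 1e-12)
  # full output-row pattern: 2 * error * Q0 at the live positions
  for (r in 3:4) for (cl in 1:4) {
    e <- which(m$W$i == r & m$W$j == cl)
    if (length(e)) {
      q <- c(-2.1, 0.3, 0, 0)[cl]
      err <- as.numeric(f$outputs[[1]])[r - 2]
      expect_equal(g$dW[e], 2 * err * q, tolerance = 1e-12)
    }
  }
})

test_that("gradients match central finite differences on random models", {
  h <- 1e-6
  cases <- list(
    list(seed = 101, N = 8L, k = 1L, I_T = 1L, param_sd = 0.3),
    list(seed = 102, N = 12L, k = 2L, I_T = 3L, param_sd = 0.5),
    list(seed = 103, N = 10L, k = 3L, I_T = 2L, param_sd = 0.2,
         zero_C = TRUE))
  for (cs in cases) {
    m <- rand_small_model(cs$seed, N = cs$N, k = cs$k,
                          param_sd = cs$param_sd,
                          zero_C_rows = if (isTRUE(cs$zero_C))
                            (cs$N - 3L):cs$N else integer(0))
    set.seed(cs$seed + 1)
    X <- replicate(cs$I_T, matrix(rnorm(2 * 2), 2, 2), simplify = FALSE)
    Y <- replicate(cs$I_T, matrix(rnorm(2 * 2), 2, 2), simplify = FALSE)
    gr <- backprop(m, X, Y)
    relerr <- function(got, want)
      abs(got - want) / pmax(1e-6, abs(want))
    for (e in seq_len(nnz(m$W))) {
      mp <- m; mp$W$x[e] <- mp$W$x[e] + h
      mm <- m; mm$W$x[e] <- mm$W$x[e] - h
      fd <- (model_loss(mp, X, Y) - model_loss(mm, X, Y)) / (2 * h)
      if (abs(fd) > 1e-7) expect_lt(relerr(gr$dW[e], fd), 1e-4)
    }
    for (s in (m$N_I + 1L):cs$N) {
      mp <- m; mp$H[s] <- mp$H[s] + h
      mm <- m; mm$H[s] <- mm$H[s] - h
      fd <- (model_loss(mp, X, Y) - model_loss(mm, X, Y)) / (2 * h)
      if (abs(fd) > 1e-7) expect_lt(relerr(gr$dH[s], fd), 1e-4)
      for (p in 1:5) {
        mp <- m; mp$C_eff[s, p] <- mp$C_eff[s, p] + h
        mm <- m; mm$C_eff[s, p] <- mm$C_eff[s, p] - h
        fd <- (model_loss(mp, X, Y) - model_loss(mm, X, Y)) / (2 * h)
        if (abs(fd) > 1e-7) expect_lt(relerr(gr$dC[s, p], fd), 1e-4)
      }
    }
  }
})

test_that("optimizer updates are exact for SGD and deterministic for Adam", {
  m <- make_model_raw(rbind(c(0, 0), c(0.5, 0)), N_I = 1L, N_O = 1L)
  cfg_sgd <- train_config(optimizer = "sgd", lr = 1, epochs = 1L)
  g0 <- list(dW = 0, dH = numeric(2), dC = matrix(0, 2, 5))
  expect_equal(optimizer_step(m, g0, cfg_sgd)$W$x, 0.5)
  g1 <- list(dW = 1, dH = numeric(2), dC = matrix(0, 2, 5))
  expect_equal(optimizer_step(m, g1, cfg_sgd)$W$x, -0.5)
  cfg_adam <- train_config(optimizer = "adam", lr = 0.1, epochs = 1L)
  a1 <- optimizer_step(m, g1, cfg_adam)
  a2 <- optimizer_step(m, g1, cfg_adam)
  expect_identical(a1$W$x, a2$W$x)
  # Adam with zero gradients leaves the model unchanged
  z <- optimizer_step(m, g0, cfg_adam)
  expect_identical(z$W$x, m$W$x)
  expect_identical(z$H, m$H)
})

test_that("probabilistic deletion removes the exact count, zeros first", {
  set.seed(5)
  n <- 100L
  ii <- rep(2:11, each = 10); jj <- rep(1:10, 10)
  W <- sparse_weights(ii, jj, rnorm(n), 12)
  pr <- delete_connections_probabilistic(W, 0.05, seed = 1)
  expect_equal(nnz(pr$W), 95L)
  expect_equal(nrow(pr$deleted), 5L)
  # zero-valued weights score exactly zero and are always removed first
  W0 <- sparse_weights(ii, jj, c(rep(0, 5), rnorm(95, 2)), 12)
  pr0 <- delete_connections_probabilistic(W0, 0.05, seed = 7)
  expect_equal(sort(pr0$deleted$x), rep(0, 5))
  # fraction 0 is a no-op
  expect_equal(nnz(delete_connections_probabilistic(W, 0, seed = 1)$W), 100L)
})

test_that("deletion probability is non-increasing in weight magnitude", {
  mags <- c(0, 0.25, 0.5, 1, 2, 4)
  W <- sparse_weights(2:7, rep(1, 6), mags, 8)
  hits <- numeric(6)
  for (trial in seq_len(10000)) {
    del <- delete_connections_probabilistic(W, 1 / 3, seed = trial)$deleted
    hits[match(del$x, mags)] <- hits[match(del$x, mags)] + 1
  }
  p <- hits / 10000
  expect_equal(p[1], 1)                # zero weight always goes
  expect_true(all(diff(p) <= 0.02))    # monotone within Monte-Carlo noise
})

test_that("redundant-neuron removal is cascading and output-preserving", {
  # input 1 -> hidden 2 -> hidden 3 -> output 5 (N = 5, capacity padding 4)
  Wd <- matrix(0, 6, 6)
  Wd[2, 1] <- 0.4; Wd[3, 2] <- 0.7; Wd[6, 3] <- -1.1
  Wd[4, 1] <- 0.9                      # hidden 4 dead-ends
  m <- make_model_raw(Wd, N_I = 1L, N_O = 1L, k = 3L)
  m$population <- cell_population(matrix(rnorm(18), 6, 3),
                                  c("input", "hidden", "hidden", "hidden",
                                    "hidden", "output"), r_s = 5)
  X <- lapply(1:5, function(i) matrix(i / 3, 1, 1))
  before <- forward(m, X)$outputs
  res <- delete_redundant_neurons(m)
  expect_setequal(res$removed, c(4L, 5L))   # 5 never had any edges
  expect_equal(nrow(res$model$population$positions), 4L)
  after <- forward(res$model, X)$outputs
  expect_identical(before, after)      # bitwise-unchanged outputs
  # fully connected chain: nothing to remove
  again <- delete_redundant_neurons(res$model)
  expect_length(again$removed, 0L)
  # cascading: cut the chain at the end, both dead hidden neurons fall
  m2 <- res$model
  keep <- !(m2$W$i == 6 & m2$W$j == 3)
  m2$W <- sparse_weights(m2$W$i[keep], m2$W$j[keep], m2$W$x[keep], m2$W$N)
  casc <- delete_redundant_neurons(m2)
  expect_setequal(casc$removed, c(2L, 3L))
  expect_identical(forward(casc$model, X)$outputs,
                   forward(m2, X)$outputs)
})

test_that("trainable-parameter count follows the explicit rule", {
  empty <- make_model_raw(matrix(0, 3, 3), N_I = 1L, N_O = 1L)
  empty$slot_active <- c(TRUE, FALSE, TRUE)
  # one output slot is the only active non-input slot, no connections
  expect_equal(count_trainable_params(empty), 6L)
  one <- make_model_raw(rbind(c(0, 0), c(1, 0)), N_I = 1L, N_O = 1L)
  expect_equal(count_trainable_params(one), 1L + 1L + 5L)
  # deletion sweeps strictly decrease the count
  m <- rand_small_model(6, N = 10L)
  c0 <- count_trainable_params(m)
  m$W <- delete_connections_probabilistic(m$W, 0.2, seed = 2)$W
  expect_lt(count_trainable_params(m), c0)
})

test_that("training reduces the loss by half within 200 epochs", {
  wins <- 0L
  for (s in 1:3) {
    m <- build_localization_model(5, 30, 30, r_RT = 60, seed = s)
    d <- synth_localization(5, 160, seed = s + 10)
    X <- t(rssi_standardize(d$rssi)); Y <- t(d$targets / d$arena)
    fit <- train_model(m, list(X), list(Y),
                       train_config(lr = 0.01, epochs = 200L, seed = s))
    if (fit$log$J_train[200] <= 0.5 * fit$log$J_train[1]) wins <- wins + 1L
  }
  expect_gte(wins, 2L)
})
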