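# Activation function, sparse weight container, structural zeros, and the
# time-stepped forward pass.

test_that("UAF special values and safety", {
  x <- seq(-5, 5, by = 0.25)
  # identity parameterization reproduces x exactly
  expect_equal(uaf(x, 1, 0, 0, -1, 0), x, tolerance = 1e-12)
  # with B = 0 both softplus arguments vanish at x = 0: f(0) = E
  expect_equal(uaf(0, 2.3, 0, 1.1, 0.7, 4.2), 4.2, tolerance = 1e-12)
  expect_equal(uaf(1, 1, 0, 0, 0, 0), log(1 + exp(1)) - log(2),
               tolerance = 1e-12)
  expect_equal(uaf(1, 1, 0, 0, 0, 0), 0.62011, tolerance = 1e-5)
  # finite for extreme inputs with any finite parameters
  big <- c(-1e6, -1e3, 1e3, 1e6)
  expect_true(all(is.finite(uaf(big, 3, -2, 0.5, 4, -1))))
  g <- uaf_gradients(big, 3, -2, 0.5, 4, -1)
  expect_true(all(vapply(g, function(v) all(is.finite(v)), logical(1))))
})

test_that("row-wise UAF equals the scalar loop", {
  set.seed(21)
  N <- 17L
  C_eff <- uaf_identity_params(N) + matrix(rnorm(5 * N, 0, 0.5), N, 5)
  X <- rnorm(N)
  want <- vapply(seq_len(N), function(i)
    uaf(X[i], C_eff[i, 1], C_eff[i, 2], C_eff[i, 3], C_eff[i, 4],
        C_eff[i, 5]), numeric(1))
  expect_equal(uaf_vector(X, C_eff), want, tolerance = 1e-15)
  # matrix form: columns are independent samples
  Xm <- matrix(rnorm(N * 4), N, 4)
  got <- uaf_vector(Xm, C_eff)
  for (b in 1:4)
    expect_equal(got[, b], uaf_vector(Xm[, b], C_eff), tolerance = 1e-15)
  expect_error(uaf_vector(rnorm(N + 1), C_eff), "rows")
})

test_that("UAF partial derivatives match central finite differences", {
  expect_equal(uaf_gradients(seq(-3, 3), 1, 0, 0, -1, 0)$dx, rep(1, 7),
               tolerance = 1e-12)
  set.seed(33)
  h <- 1e-6
  for (case in 1:20) {
    x <- rnorm(1, 0, 2)
    th <- rnorm(5, 0, 1)
    if (case %% 5 == 0) th[3] <- 0  # the |C| kink: subgradient 0 at C = 0
    g <- uaf_gradients(x, th[1], th[2], th[3], th[4], th[5])
    expect_equal(g$dE, 1)
    fd <- function(pert_x, pert_th) {
      (uaf(x + pert_x * h, th[1] + pert_th[1] * h, th[2] + pert_th[2] * h,
           th[3] + pert_th[3] * h, th[4] + pert_th[4] * h,
           th[5] + pert_th[5] * h) -
         uaf(x - pert_x * h, th[1] - pert_th[1] * h, th[2] - pert_th[2] * h,
             th[3] - pert_th[3] * h, th[4] - pert_th[4] * h,
             th[5] - pert_th[5] * h)) / (2 * h)
    }
    grads <- c(g$dx, g$dA, g$dB, g$dC, g$dD)
    for (p in 1:5) {
      pert_x <- as.numeric(p == 1)
      pert_th <- as.numeric(seq_len(5) == (p - 1))
      want <- fd(pert_x, pert_th)
      expect_equal(grads[p], want, tolerance = 1e-5)
    }
  }
})

test_that("sparse weights: ordering, capacity, duplicates", {
  W <- sparse_weights(c(3, 1, 2), c(1, 2, 2), c(0.3, 0.1, 0.2), 4)
  expect_equal(W$i, c(1L, 2L, 3L))     # row-major entry order
  expect_equal(W$x, c(0.1, 0.2, 0.3))
  expect_equal(nnz(W), 3L)
  expect_error(sparse_weights(c(1, 1), c(2, 2), c(1, 2), 4), "duplicate")
  expect_error(sparse_weights(1, 5, 1, 4), "out of")
})

test_that("structural zeroing removes exactly the forbidden regions", {
  N <- 6L; N_I <- 2L; N_O <- 2L
  full <- expand.grid(i = 1:N, j = 1:N)
  W <- sparse_weights(full$i, full$j, seq_len(N * N), N)
  Z <- enforce_structural_zeros(W, N_I, N_O)
  expect_true(all(Z$i > N_I))
  expect_true(all(Z$j <= N - N_O))
  expect_true(all(Z$i != Z$j))
  expect_equal(nnz(Z), (N - N_I) * (N - N_O) - (N - N_I - N_O))
  # already-compliant matrices pass through unchanged
  Z2 <- enforce_structural_zeros(Z, N_I, N_O)
  expect_identical(Z2, Z)
  # self-loops retained on request, rows/cols still zeroed
  S <- enforce_structural_zeros(W, N_I, N_O, allow_self_loops = TRUE)
  expect_true(any(S$i == S$j))
  expect_true(all(S$i > N_I & S$j <= N - N_O))
})

test_that("Xavier initialization respects fan bounds and determinism", {
  expect_equal(nnz(init_weights_xavier(integer(0), integer(0), 8)), 0L)
  W1 <- init_weights_xavier(3, 2, 8, seed = 4)
  expect_lte(abs(W1$x), sqrt(3))       # fan_in = fan_out = 1
  W2 <- init_weights_xavier(3, 2, 8, seed = 4)
  expect_identical(W1, W2)
  set.seed(10)
  rows <- sample(3:8, 40, replace = TRUE)
  cols <- sample(1:6, 40, replace = TRUE)
  keep <- !duplicated(paste(rows, cols))
  rows <- rows[keep]; cols <- cols[keep]
  W <- init_weights_xavier(rows, cols, 8, seed = 1)
  fi <- tabulate(W$i, 8)[W$i]; fo <- tabulate(W$j, 8)[W$j]
  expect_true(all(abs(W$x) <= sqrt(6 / (fi + fo))))
})

test_that("forward pass reproduces the worked single-step example", {
  m <- make_model_raw(worked_example_W(), N_I = 2L, N_O = 2L, k = 1L)
  f <- forward(m, list(c(-2.1, 0.3)))
  expect_equal(as.numeric(f$states[[2]]), c(0.03, 1.68, -2.31, 4.05),
               tolerance = 1e-12)
  expect_equal(as.numeric(f$outputs[[1]]), c(-2.31, 4.05), tolerance = 1e-12)
  # zero inputs, zero bias, identity activation: everything stays zero
  fz <- forward(m, list(c(0, 0), c(0, 0)))
  expect_true(all(vapply(fz$outputs, function(y) all(y == 0), logical(1))))
})

test_that("forward equals a layered feed-forward oracle at k = depth", {
  set.seed(8)
  N <- 12L
  W1 <- matrix(rnorm(6), 3, 2)   # input(2) -> h1(3)
  W2 <- matrix(rnorm(9), 3, 3)   # h1 -> h2
  W3 <- matrix(rnorm(6), 2, 3)   # h2 -> out(2)
  Wd <- matrix(0, N, N)
  Wd[3:5, 1:2] <- W1
  Wd[6:8, 3:5] <- W2
  Wd[11:12, 6:8] <- W3
  C_eff <- uaf_identity_params(N)
  C_eff[3:8, ] <- C_eff[3:8, ] + matrix(rnorm(30, 0, 0.3), 6, 5)
  m <- make_model_raw(Wd, N_I = 2L, N_O = 2L, k = 3L, C_eff = C_eff)
  x <- c(0.7, -1.2)
  f <- forward(m, list(x))
  h1 <- uaf_vector(as.numeric(W1 %*% x), C_eff[3:5, ])
  h2 <- uaf_vector(as.numeric(W2 %*% h1), C_eff[6:8, ])
  yhat <- as.numeric(W3 %*% h2)        # output rows keep identity UAF
  expect_equal(as.numeric(f$outputs[[1]]), yhat, tolerance = 1e-12)
})

test_that("linear forward satisfies S(t+1) = W Q(t) and causality", {
  set.seed(14)
  m <- rand_small_model(14, N = 9L, N_I = 2L, N_O = 2L, k = 2L,
                        param_sd = 0)   # identity UAF
  m$H <- numeric(9)
  Wm <- matrix(0, 9, 9)
  Wm[cbind(m$W$i, m$W$j)] <- m$W$x
  X <- list(rnorm(2), rnorm(2), rnorm(2))
  f <- forward(m, X, record = TRUE)
  for (t0 in seq_along(f$Q))
    expect_equal(f$states[[t0 + 1]], Wm %*% f$Q[[t0]], tolerance = 1e-12,
                 ignore_attr = TRUE)
  # causality: when every input-to-output path is at least k steps long,
  # perturbing X(t+1) leaves Yhat(t) unchanged (layered fixture, depth 3)
  set.seed(15)
  Wd <- matrix(0, 12, 12)
  Wd[3:5, 1:2] <- rnorm(6); Wd[6:8, 3:5] <- rnorm(9)
  Wd[11:12, 6:8] <- rnorm(6)
  ml <- make_model_raw(Wd, N_I = 2L, N_O = 2L, k = 3L)
  Xl <- list(rnorm(2), rnorm(2), rnorm(2))
  Xp <- Xl; Xp[[2]] <- Xp[[2]] + 5; Xp[[3]] <- Xp[[3]] - 7
  fl <- forward(ml, Xl); fp <- forward(ml, Xp)
  expect_identical(fl$outputs[[1]], fp$outputs[[1]])
  expect_false(identical(fl$outputs[[2]], fp$outputs[[2]]))
})

test_that("input length mismatches are rejected", {
  m <- make_model_raw(worked_example_W(), 2L, 2L)
  expect_error(forward(m, list(c(1, 2, 3))), "N_I")
})
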