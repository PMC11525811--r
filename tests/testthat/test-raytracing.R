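# Occlusion predicate, the three ray-tracing algorithms, connectivity
# verification, and the analytic connection-length distribution.

test_that("occlusion predicate: boundary behaviour and oracle agreement", {
  p_i <- c(0, 0, 0); p_j <- c(8, 0, 0)
  expect_false(segment_blocked(p_i, p_j, matrix(numeric(0), 0, 3)))
  # obstacle at the midpoint offset exactly r_n: boundary inclusive
  expect_true(segment_blocked(p_i, p_j, rbind(c(4, 1, 0))))
  expect_false(segment_blocked(p_i, p_j, rbind(c(4, 1 + 1e-9, 0))))
  # behind / beyond the endpoints never blocks
  expect_false(segment_blocked(p_i, p_j, rbind(c(-1, 0.5, 0))))
  expect_false(segment_blocked(p_i, p_j, rbind(c(9, 0.5, 0))))
  expect_error(segment_blocked(p_i, p_i, rbind(c(1, 1, 1))), "zero-length")
  # 1000 random configurations against the point-to-segment oracle
  set.seed(99)
  for (case in seq_len(1000)) {
    pi_ <- runif(3, -5, 5); pj_ <- runif(3, -5, 5)
    obst <- matrix(runif(3 * 8, -5, 5), 8, 3)
    expect_identical(as.logical(segment_blocked(pi_, pj_, obst)),
                     occlusion_oracle(pi_, pj_, obst))
  }
})

test_that("first blocker reported is the nearest along the segment", {
  p_i <- c(0, 0, 0); p_j <- c(10, 0, 0)
  obst <- rbind(c(7, 0.2, 0), c(3, 0.2, 0), c(5, 0.2, 0))
  b <- segment_blocked(p_i, p_j, obst)
  expect_true(as.logical(b))
  expect_equal(attr(b, "blocker"), 2L)
})

test_that("RT-1 finds mutually visible neurons and respects blockers", {
  # single isolated neuron: nothing to hit
  lone <- cell_population(matrix(0, 1, 3), "hidden", r_s = 1)
  expect_equal(nrow(rt1(lone, K = 100, seed = 1)), 0L)
  # two neurons, no glia: with K = 10^4 the disc subtends enough solid
  # angle that both directed edges appear with probability ~1
  two <- cell_population(rbind(c(0, 0, 0), c(6, 0, 0)),
                         c("hidden", "hidden"), r_s = 10)
  e <- rt1(two, K = 10000, seed = 5)
  expect_setequal(paste(e$source, e$target), c("1 2", "2 1"))
  expect_equal(e$length, c(6, 6))
  # three collinear neurons: the middle one is always the nearest hit
  three <- cell_population(rbind(c(0, 0, 0), c(4, 0, 0), c(8, 0, 0)),
                           rep("hidden", 3), r_s = 10)
  e3 <- rt1(three, K = 5000, seed = 7)
  expect_false("1 3" %in% paste(e3$source, e3$target))
  expect_false("3 1" %in% paste(e3$source, e3$target))
  # a glial cell on the segment blocks the pair entirely
  glia <- cell_population(rbind(c(0, 0, 0), c(6, 0, 0), c(3, 0, 0)),
                          c("hidden", "hidden", "glial"), r_s = 10)
  eg <- rt1(glia, K = 4000, seed = 3)
  expect_equal(nrow(eg), 0L)
})

test_that("RT-2 equals the brute-force occlusion oracle", {
  two <- cell_population(rbind(c(0, 0, 0), c(6, 0, 0)),
                         c("hidden", "hidden"), r_s = 10)
  expect_setequal(edge_keys(rt2(two)), c("1 2", "2 1"))
  mid <- cell_population(rbind(c(0, 0, 0), c(6, 0, 0), c(3, 0, 0)),
                         c("hidden", "hidden", "glial"), r_s = 10)
  expect_equal(nrow(rt2(mid)), 0L)
  for (seed in 1:4) {
    pop <- rand_population(seed, 50, extent = 8)
    got <- rt2(pop, seed = seed)
    neur <- which(pop$cell_type != "glial")
    want <- character(0)
    for (i in neur) for (j in neur) if (i != j) {
      if (!segment_blocked(pop$positions[i, ], pop$positions[j, ],
                           pop$positions[-c(i, j), , drop = FALSE]))
        want <- c(want, paste(i, j))
    }
    expect_setequal(paste(got$source, got$target), want)
    # occlusion soundness: re-check every emitted edge against all cells
    for (r in seq_len(nrow(got))) {
      i <- got$source[r]; j <- got$target[r]
      expect_false(as.logical(
        segment_blocked(pop$positions[i, ], pop$positions[j, ],
                        pop$positions[-c(i, j), , drop = FALSE])))
    }
  }
})

test_that("single-cluster RT-3 equals RT-2 exactly and bounds edge length", {
  pop <- rand_population(12, 120, extent = 6, ball = TRUE)
  r2e <- rt2(pop, seed = 1)
  r3e <- rt3(pop, r_RT = 4 * pop$r_s, seed = 1, verify = FALSE)
  expect_setequal(edge_keys(r3e), edge_keys(r2e))
  # distance-limited tracing never emits edges longer than 2 r_RT
  r3s <- rt3(pop, r_RT = 3, seed = 2, verify = FALSE)
  expect_true(all(r3s$length <= 2 * 3 + 1e-12))
  # edge lengths equal the Euclidean endpoint distances
  d <- sqrt(rowSums((pop$positions[r3s$source, ] -
                       pop$positions[r3s$target, ])^2))
  expect_equal(r3s$length, d, tolerance = 1e-12)
})

test_that("deduplication is idempotent and drops repeated pairs", {
  conn <- connection_set(c(1, 2, 1, 1), c(2, 3, 2, 3), c(1, 1, 1, 2))
  d1 <- dedup_connections(conn)
  expect_equal(nrow(d1), 3L)
  expect_identical(dedup_connections(d1), d1)
})

test_that("input-output connectivity report agrees with a closure oracle", {
  # chain input -> hidden -> output
  chain <- connection_set(c(1, 2), c(2, 3), c(1, 1))
  rep <- verify_io_connectivity(chain, N_I = 1, N_O = 1, n_neurons = 3)
  expect_true(rep$all_connected)
  # an input with no outgoing edges is flagged
  rep2 <- verify_io_connectivity(chain, N_I = 2, N_O = 1, n_neurons = 4)
  expect_false(rep2$all_connected)
  expect_equal(rep2$per_input$ok, c(FALSE, FALSE))
  # random DAGs vs Floyd-Warshall transitive closure
  for (seed in 1:5) {
    set.seed(seed)
    n <- 30L; N_I <- 4L; N_O <- 3L
    A <- matrix(FALSE, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      A[i, j] <- runif(1) < 0.08
    eij <- which(A, arr.ind = TRUE)
    conn <- connection_set(eij[, 1], eij[, 2], rep(1, nrow(eij)))
    R <- A; diag(R) <- TRUE
    for (k in 1:n) R <- R | (R[, k] %o% R[k, ])
    want <- vapply(seq_len(N_I), function(i)
      all(R[i, seq.int(n - N_O + 1L, n)]), logical(1))
    got <- verify_io_connectivity(conn, N_I, N_O, n_neurons = n)
    expect_equal(got$per_input$ok, want)
  }
})

test_that("analytic length distribution: normalization, limit, mode", {
  r_m <- 7
  # integrates to one within 1e-8
  f <- function(r) connection_pdf_analytic(r, r_m, eta_T = 1e-3)
  I <- integrate(f, 0, 2 * r_m, rel.tol = 1e-12)$value
  expect_lt(abs(I - 1), 1e-8)
  # zero at both support ends and outside
  expect_equal(f(0), 0)
  expect_equal(f(2 * r_m), 0)
  expect_equal(f(2 * r_m + 1), 0)
  expect_equal(f(-1), 0)
  # zero-density limit of the normalization constant: 3 / (16 r_m^6)
  expect_equal(connection_pdf_const(r_m, eta_T = 0), 3 / (16 * r_m^6),
               tolerance = 1e-10)
  # zero-density mode at the positive root of 5 r^3 - 36 r_m^2 r + 32 r_m^3
  mode <- optimize(function(r) connection_pdf_analytic(r, r_m, 0),
                   c(0, 2 * r_m), maximum = TRUE)$maximum
  # (u = 2 is the trivial endpoint root; the interior root is the mode)
  root <- uniroot(function(u) 5 * u^3 - 36 * u + 32, c(0.5, 1.5))$root
  expect_equal(mode / r_m, root, tolerance = 1e-4)
  expect_equal(mode / r_m, 1.0494, tolerance = 1e-3)
})

test_that("unblocked-segment probability is clamped and monotone", {
  expect_equal(connection_prob_unblocked(0, 1e-3), 1)
  r0 <- 1 / (pi * 1e-3)
  expect_equal(connection_prob_unblocked(r0, 1e-3), 0)
  expect_equal(connection_prob_unblocked(r0 * 2, 1e-3), 0)
  r <- seq(0, 400, by = 10)
  p <- connection_prob_unblocked(r, 1e-3)
  expect_true(all(diff(p) <= 0))
})

test_that("out-degree statistics summarize the traced graph", {
  pop <- cell_population(rbind(c(0, 0, 0), c(6, 0, 0)),
                         c("hidden", "hidden"), r_s = 10)
  expect_equal(connections_per_neuron(pop, connection_set())$mean_out_degree, 0)
  expect_equal(connections_per_neuron(pop, rt2(pop))$mean_out_degree, 1)
})
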