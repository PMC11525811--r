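# Collision detection between cells and collision-free sphere population.
#
# Cells of radius r_n collide when their centers are within 2 r_n
# (inclusive). Detection at scale uses a uniform spatial grid with bin side
# 2 r_n, so only the 27 neighbouring bins of a cell ever need checking.

# Encode integer 3D bin coordinates into one exact double key.
# Bins are offset so coordinates up to +-1023 bins (~ +-2046 r_n) encode
# exactly; keys stay below 2^33 which doubles represent exactly.
.bin_key <- function(P, cell_size) {
  b <- floor(P / cell_size) + 1024
  if (any(b < 0 | b > 2047)) stop("coordinates out of grid-key range")
  (b[, 1L] * 2048 + b[, 2L]) * 2048 + b[, 3L]
}

.grid_offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))

# All (i, j) pairs with |P[i] - P[j]| <= radius, i != j, returned one row
# per ordered pair found (each unordered pair appears in both orders).
# Query points are processed against a keyed table bin by bin; memory is
# bounded by the number of candidate pairs, never M^2.
.neighbor_pairs <- function(P, radius, Q = NULL, chunk_size = 65536L) {
  same <- is.null(Q)
  if (same) Q <- P
  if (nrow(P) == 0L || nrow(Q) == 0L)
    return(data.table::data.table(i = integer(0), j = integer(0)))
  kP <- .bin_key(P, radius)
  ref <- data.table::data.table(bk = kP, i = seq_len(nrow(P)))
  data.table::setkey(ref, bk)
  bQ <- floor(Q / radius) + 1024
  out <- vector("list", nrow(.grid_offsets))
  for (s in seq_len(nrow(.grid_offsets))) {
    bs <- sweep(bQ, 2L, .grid_offsets[s, ], "+")
    kq <- (bs[, 1L] * 2048 + bs[, 2L]) * 2048 + bs[, 3L]
    q <- data.table::data.table(bk = kq, j = seq_len(nrow(Q)))
    m <- ref[q, on = "bk", allow.cartesian = TRUE, nomatch = NULL]
    if (same) m <- m[m$i != m$j, ]
    if (nrow(m)) {
      d2 <- (P[m$i, 1L] - Q[m$j, 1L])^2 + (P[m$i, 2L] - Q[m$j, 2L])^2 +
        (P[m$i, 3L] - Q[m$j, 3L])^2
      m <- m[d2 <= radius^2, ]
    }
    out[[s]] <- m
  }
  data.table::rbindlist(out)
}

#' Detect colliding cells
#'
#' Flags every cell whose center lies within `2 r_n` (inclusive) of another
#' cell's center. Three algorithms with identical results are provided:
#' `serial` checks one cell per pass against all others, `batch` forms the
#' all-pairs distance structure at once, and `minibatch` processes cells in
#' fixed-size chunks against a uniform spatial grid and never materializes
#' the full pairwise distance structure (the only practical choice beyond
#' ~10^4 cells).
#'
#' @param positions an `M x 3` position matrix.
#' @param r_n cell radius (default 1).
#' @param method one of `"serial"`, `"batch"`, `"minibatch"`.
#' @param exempt optional integer indices of cells excluded from the check
#'   entirely (e.g. co-located output neurons or stacked input channels).
#' @return sorted integer vector of colliding cell indices.
#' @export
detect_collisions <- function(positions, r_n = 1,
                              method = c("minibatch", "serial", "batch"),
                              exempt = NULL) {
  method <- match.arg(method)
  P <- as.matrix(positions)
  if (!all(is.finite(P))) stop("detect_collisions: positions must be finite")
  M <- nrow(P)
  act <- setdiff(seq_len(M), exempt)
  if (length(act) < 2L) return(integer(0))
  A <- P[act, , drop = FALSE]
  thr2 <- (2 * r_n)^2
  hit <- switch(method,
    serial = {
      h <- logical(length(act))
      for (i in seq_along(act)) {
        d2 <- (A[, 1L] - A[i, 1L])^2 + (A[, 2L] - A[i, 2L])^2 +
          (A[, 3L] - A[i, 3L])^2
        d2[i] <- Inf
        h[i] <- any(d2 <= thr2)
      }
      h
    },
    batch = {
      D <- as.matrix(stats::dist(A))
      diag(D) <- Inf
      apply(D <= 2 * r_n, 1L, any)
    },
    minibatch = {
      h <- logical(length(act))
      n <- length(act)
      chunk <- 65536L
      for (lo in seq(1L, n, by = chunk)) {
        hi <- min(lo + chunk - 1L, n)
        idx <- lo:hi
        pr <- .neighbor_pairs(A, 2 * r_n, Q = A[idx, , drop = FALSE])
        pr <- pr[pr$i != idx[pr$j], ]
        h[idx[unique(pr$j)]] <- TRUE
      }
      h
    })
  sort(act[hit])
}

#' Geometry configuration for building a population
#'
#' @param N_hidden,N_glial,N_input,N_output cell counts (non-negative).
#' @param r_s requested sphere radius; the realized radius is
#'   `max(r_s, min_sphere_radius(N_T, P_c_th))` so the collision-probability
#'   target is always honoured. `NULL` means use the minimum radius.
#' @param P_c_th collision-probability threshold in (0, 1).
#' @param input_layout list describing the surface layout: one of
#'   `list(type = "grid", N_x =, N_y =)`, `list(type = "helix", N_1D =)`,
#'   `list(type = "stacked", N_x =, N_y =, C =)` or `list(type = "random")`.
#'   The default lays `N_input` features out in helix order.
#' @param seed integer seed; every random draw derives a sub-stream from it.
#' @return a `geometry_config` list.
#' @export
geometry_config <- function(N_hidden, N_glial, N_input, N_output,
                            r_s = NULL, P_c_th = 0.01,
                            input_layout = NULL, seed = 1L) {
  stopifnot(N_hidden >= 0, N_glial >= 0, N_input >= 0, N_output >= 0,
            P_c_th > 0, P_c_th < 1)
  if (is.null(input_layout)) input_layout <- list(type = "helix", N_1D = N_input)
  if (identical(input_layout$type, "grid") &&
      input_layout$N_x * input_layout$N_y < N_input)
    stop("geometry_config: grid layout smaller than N_input")
  structure(list(N_hidden = as.integer(N_hidden), N_glial = as.integer(N_glial),
                 N_input = as.integer(N_input), N_output = as.integer(N_output),
                 r_s = r_s, P_c_th = P_c_th, input_layout = input_layout,
                 seed = as.integer(seed)),
            class = "geometry_config")
}

#' Construct a cell population object
#'
#' @param positions `M x 3` Cartesian position matrix (units of `r_n`).
#' @param cell_type character vector of `"input"`, `"hidden"`, `"output"`,
#'   `"glial"` per row.
#' @param r_s sphere radius; `r_n` cell radius.
#' @param input_site optional site index for stacked (co-located) inputs.
#' @return a `cell_population` list with derived counts.
#' @export
cell_population <- function(positions, cell_type, r_s, r_n = 1,
                            input_site = NULL) {
  positions <- as.matrix(positions)
  stopifnot(nrow(positions) == length(cell_type))
  colnames(positions) <- c("x", "y", "z")
  structure(list(positions = positions, cell_type = cell_type,
                 r_s = r_s, r_n = r_n, input_site = input_site),
            class = "cell_population")
}

#' @export
print.cell_population <- function(x, ...) {
  ct <- table(factor(x$cell_type, levels = c("input", "hidden", "output", "glial")))
  cat(sprintf("<cell_population> %d cells in sphere r_s = %.4g r_n\n",
              nrow(x$positions), x$r_s))
  cat(sprintf("  input %d | hidden %d | output %d | glial %d\n",
              ct[["input"]], ct[["hidden"]], ct[["output"]], ct[["glial"]]))
  invisible(x)
}

#' Counts per cell type
#' @param population a `cell_population`.
#' @return named integer vector with `N_I`, `N_h`, `N_O`, `N_g`.
#' @export
population_counts <- function(population) {
  c(N_I = sum(population$cell_type == "input"),
    N_h = sum(population$cell_type == "hidden"),
    N_O = sum(population$cell_type == "output"),
    N_g = sum(population$cell_type == "glial"))
}

# Sequentially accept candidate positions, rejecting any candidate within
# 2 r_n of a previously accepted (or fixed) cell. Exact sequential
# semantics, evaluated in batches for speed: within a batch a candidate is
# re-examined only if it collides with an earlier accepted candidate.
.accept_reject <- function(n, r_s, r_n, fixed = NULL, seed = 1L,
                           max_rounds = 50L) {
  acc <- matrix(numeric(0), 0L, 3L)
  n_attempt <- 0L; n_reject <- 0L
  round <- 0L
  while (nrow(acc) < n) {
    round <- round + 1L
    if (round > max_rounds)
      stop("populate_sphere: could not place cells without collisions (packing too dense)")
    need <- n - nrow(acc)
    cand <- sample_hidden_positions(need, r_s, seed = derive_seed(seed, paste0("place", round)))
    n_attempt <- n_attempt + need
    blockers <- rbind(fixed, acc)
    bad <- logical(need)
    if (nrow(blockers)) {
      pr <- .neighbor_pairs(blockers, 2 * r_n, Q = cand)
      bad[unique(pr$j)] <- TRUE
    }
    # within-batch sequential resolution
    self <- .neighbor_pairs(cand, 2 * r_n)
    self <- self[self$i < self$j, ]
    if (nrow(self)) {
      ord <- order(self$j, self$i)
      si <- self$i[ord]; sj <- self$j[ord]
      for (p in seq_along(sj)) if (!bad[si[p]]) bad[sj[p]] <- TRUE
    }
    n_reject <- n_reject + sum(bad)
    acc <- rbind(acc, cand[!bad, , drop = FALSE])
  }
  list(positions = acc, n_attempt = n_attempt, n_reject = n_reject)
}

#' Populate the network sphere with a collision-free cell population
#'
#' Input neurons are first laid out on the sphere surface according to the
#' configured layout and output neurons are fixed at the origin. Hidden
#' neurons and glial cells are then sampled uniformly in the ball and
#' accepted sequentially, rejecting any candidate whose center falls within
#' `2 r_n` of a previously accepted cell (or of an input neuron); rejected
#' candidates are replaced by fresh draws. Output neurons are exempt from
#' the separation rule (they are co-located at the origin), as are stacked
#' input channels sharing a site. The realized sphere radius is
#' `max(config$r_s, min_sphere_radius(N_T, P_c_th))`.
#'
#' The realized sequential rejection fraction is recorded in the
#' `rejection` attribute; at density `eta_T` it approaches half the
#' analytic collision probability [collision_probability_analytic()]
#' because the i-th candidate only sees the cells accepted before it.
#'
#' @param config a [geometry_config()].
#' @param r_n cell radius (default 1).
#' @return a [cell_population()] ordered input, hidden, output, glial, with
#'   attribute `rejection = list(n_attempt, n_reject, fraction)`.
#' @export
populate_sphere <- function(config, r_n = 1) {
  stopifnot(inherits(config, "geometry_config"))
  N_T <- config$N_hidden + config$N_glial
  r_min <- if (N_T >= 1) min_sphere_radius(max(N_T, 1), config$P_c_th) else 0
  r_s <- max(config$r_s %||% 0, r_min)
  if (r_s <= 0) r_s <- 1
  lay <- config$input_layout
  site <- NULL
  P_in <- if (config$N_input == 0L) {
    matrix(numeric(0), 0L, 3L)
  } else switch(lay$type,
    grid = {
      G <- place_input_grid(lay$N_x, lay$N_y, r_s)
      G[seq_len(config$N_input), , drop = FALSE]
    },
    helix = place_input_helix(lay$N_1D %||% config$N_input, r_s)[
      seq_len(config$N_input), , drop = FALSE],
    stacked = {
      G <- place_input_stacked(lay$N_x, lay$N_y, lay$C, r_s)
      site <- attr(G, "site")[seq_len(config$N_input)]
      G[seq_len(config$N_input), , drop = FALSE]
    },
    random = {
      set.seed(derive_seed(config$seed, "input-random"))
      theta <- acos(2 * (runif(config$N_input) - 0.5))
      phi <- 2 * pi * runif(config$N_input)
      sph_to_cart(r_s, theta, phi)
    },
    stop("unknown input layout type"))
  P_out <- matrix(0, config$N_output, 3L)
  # distinct input sites act as fixed blockers for interior cells
  hg <- .accept_reject(N_T, r_s, r_n, fixed = P_in, seed = config$seed)
  n_h <- config$N_hidden
  idx_h <- seq_len(n_h)
  P_hid <- hg$positions[idx_h, , drop = FALSE]
  P_gli <- hg$positions[setdiff(seq_len(N_T), idx_h), , drop = FALSE]
  pop <- cell_population(
    positions = rbind(P_in, P_hid, P_out, P_gli),
    cell_type = c(rep("input", nrow(P_in)), rep("hidden", nrow(P_hid)),
                  rep("output", nrow(P_out)), rep("glial", nrow(P_gli))),
    r_s = r_s, r_n = r_n, input_site = site)
  attr(pop, "rejection") <- list(n_attempt = hg$n_attempt,
                                 n_reject = hg$n_reject,
                                 fraction = hg$n_reject / max(1L, hg$n_attempt))
  pop
}
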