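# Connection formation by ray tracing with line-of-sight occlusion.
#
# A candidate connection i -> j is vetoed when a third cell k lies within
# r_n (inclusive) of the segment AND strictly between the endpoints:
#   (r_k - r_i) . (r_j - r_i) > 0  and  (r_k - r_j) . (r_i - r_j) > 0.
# Edges are directed and deduplicated; edge lengths equal the Euclidean
# distance between the endpoint cells.

#' Construct a connection set
#'
#' @param source,target integer neuron indices (1-based, population order
#'   with inputs first and outputs last among neurons).
#' @param length Euclidean segment lengths in `r_n` units.
#' @return a `connection_set` data.frame with columns source, target, length.
#' @export
connection_set <- function(source = integer(0), target = integer(0),
                           length = numeric(0)) {
  structure(data.frame(source = as.integer(source),
                       target = as.integer(target),
                       length = as.numeric(length)),
            class = c("connection_set", "data.frame"))
}

#' Remove duplicate directed edges
#'
#' Keeps the first occurrence of every (source, target) pair. Applying the
#' operation twice equals applying it once.
#'
#' @param conn a [connection_set()].
#' @return the deduplicated connection set.
#' @export
dedup_connections <- function(conn) {
  keep <- !duplicated(conn[, c("source", "target")])
  structure(conn[keep, , drop = FALSE], class = class(conn))
}

#' Line-of-sight occlusion predicate
#'
#' Tests whether the open segment from `p_i` to `p_j` is blocked by any of
#' the obstacle cells: an obstacle blocks when its perpendicular distance
#' to the segment line is `<= r_n` (boundary inclusive) and it lies
#' strictly between the endpoints. The endpoints themselves (zero offset or
#' co-located cells) never block.
#'
#' @param p_i,p_j endpoint coordinates (length-3 vectors), `p_i != p_j`.
#' @param obstacles `m x 3` matrix of obstacle centers (may be empty).
#' @param r_n cell radius.
#' @return logical; attribute `blocker` holds the index of the first
#'   blocking obstacle along the segment (`NA` when unblocked).
#' @export
segment_blocked <- function(p_i, p_j, obstacles, r_n = 1) {
  d <- as.numeric(p_j) - as.numeric(p_i)
  L2 <- sum(d^2)
  if (L2 == 0) stop("segment_blocked: zero-length segment")
  O <- matrix(as.numeric(obstacles), ncol = 3L)
  if (nrow(O) == 0L) {
    out <- FALSE; attr(out, "blocker") <- NA_integer_; return(out)
  }
  D <- sweep(O, 2L, as.numeric(p_i))
  G <- as.numeric(D %*% d)
  between <- G > 0 & G < L2
  perp2 <- rowSums(D^2) - G^2 / L2
  blk <- between & perp2 <= r_n^2
  out <- any(blk)
  attr(out, "blocker") <- if (out) which(blk)[which.min(G[blk])] else NA_integer_
  out
}

# Resolve hits on co-located target groups: among unblocked targets of one
# source that share an exact position, keep one chosen uniformly at random.
.resolve_colocated <- function(targets, P) {
  if (length(targets) < 2L) return(targets)
  key <- paste(P[targets, 1L], P[targets, 2L], P[targets, 3L])
  if (!anyDuplicated(key)) return(targets)
  grp <- split(targets, key)
  out <- vapply(grp, function(g)
    if (length(g) == 1L) g else g[sample.int(length(g), 1L)], integer(1))
  sort(unname(out))
}

# Pairwise visibility within one set of cells (the RT-2 kernel).
# P: m x 3 positions of all member cells (these are also the only
# obstacles); neuron_idx: which rows are neurons. Returns a data.frame of
# local-index edges.
.rt2_core <- function(P, neuron_idx, r_n = 1, resolve_sites = TRUE) {
  m <- nrow(P)
  n_src <- length(neuron_idx)
  if (n_src < 2L) return(data.frame(source = integer(0), target = integer(0),
                                    length = numeric(0)))
  src_l <- vector("list", n_src)
  for (a in seq_len(n_src)) {
    i <- neuron_idx[a]
    D <- sweep(P, 2L, P[i, ])                       # m x 3, rows r_k - r_i
    tg <- neuron_idx[neuron_idx != i]
    Dn <- D[tg, , drop = FALSE]
    pos <- rowSums(Dn^2) > 0
    tg <- tg[pos]; Dn <- Dn[pos, , drop = FALSE]
    if (!length(tg)) next
    G <- D %*% t(Dn)                                # m x n_targets
    # take |d_j|^2 from the same Gram product so that the strict
    # betweenness test G < L2 excludes the target (and any cell
    # co-located with it) exactly, with no last-ulp mismatch
    L2 <- G[cbind(tg, seq_along(tg))]
    r2 <- rowSums(D^2)
    blocked <- (G > 0) & sweep(G, 2L, L2, "<") &
      (sweep(-(G^2), 2L, L2, "/") + r2) <= r_n^2
    open <- tg[colSums(blocked) == 0L]
    if (resolve_sites) open <- .resolve_colocated(open, P)
    if (length(open))
      src_l[[a]] <- data.frame(source = i, target = open,
                               length = sqrt(L2[match(open, tg)]))
  }
  out <- do.call(rbind, src_l[!vapply(src_l, is.null, TRUE)])
  if (is.null(out)) data.frame(source = integer(0), target = integer(0),
                               length = numeric(0)) else out
}

# Extract positions / neuron bookkeeping shared by the RT drivers.
.rt_prep <- function(population) {
  P <- population$positions
  is_neuron <- population$cell_type != "glial"
  list(P = P, neuron_idx = which(is_neuron), M = nrow(P))
}

#' RT-1: connections from randomly generated rays
#'
#' Every neuron emits `K` rays with directions uniform on the unit sphere.
#' Each ray terminates at the nearest cell it intersects (a cell intersects
#' when its perpendicular distance to the ray is `<= r_n` ahead of the
#' origin): a glial hit discards the ray, a neuron hit creates a directed
#' edge from the emitting neuron. Ties at identical parametric distance
#' resolve to a random member for co-located cells and otherwise to the
#' lowest cell index. Duplicate edges are removed.
#'
#' @param population a [cell_population()].
#' @param K rays per neuron (default 10000).
#' @param seed integer seed (per-neuron sub-streams are derived from it).
#' @param ray_chunk rays processed per block (memory control).
#' @return a [connection_set()].
#' @export
rt1 <- function(population, K = 10000L, seed = 1L, ray_chunk = 4096L) {
  stopifnot(K >= 1)
  rp <- .rt_prep(population)
  P <- rp$P; M <- rp$M
  glial <- population$cell_type == "glial"
  edges <- list()
  for (i in rp$neuron_idx) {
    set.seed(derive_seed(seed, paste0("rt1-", i)))
    D <- sweep(P, 2L, P[i, ])                      # m x 3
    r2 <- rowSums(D^2)
    hits <- integer(0)
    done <- 0L
    while (done < K) {
      kk <- min(ray_chunk, K - done); done <- done + kk
      th <- acos(2 * (runif(kk) - 0.5)); ph <- 2 * pi * runif(kk)
      U <- sph_to_cart(1, th, ph)                  # kk x 3 unit directions
      Tm <- D %*% t(U)                             # m x kk parametric dists
      isect <- (Tm > 0) & (r2 - Tm^2 <= population$r_n^2)
      Tm[!isect] <- Inf
      nearest_t <- apply(Tm, 2L, min)
      hit_ray <- which(is.finite(nearest_t))
      for (rr in hit_ray) {
        cand <- which(Tm[, rr] == nearest_t[rr])
        k <- if (length(cand) == 1L) cand else {
          key <- paste(P[cand, 1L], P[cand, 2L], P[cand, 3L])
          if (length(unique(key)) == 1L) cand[sample.int(length(cand), 1L)]
          else min(cand)
        }
        if (!glial[k]) hits <- c(hits, k)
      }
    }
    hits <- unique(hits)
    if (length(hits))
      edges[[length(edges) + 1L]] <-
        data.frame(source = i, target = hits, length = sqrt(r2[hits]))
  }
  out <- if (length(edges)) do.call(rbind, edges) else
    data.frame(source = integer(0), target = integer(0), length = numeric(0))
  dedup_connections(structure(out, class = c("connection_set", "data.frame")))
}

#' RT-2: all-pairs directly connected rays with occlusion
#'
#' For every ordered neuron pair (i, j), a directed edge i -> j is created
#' unless any other cell blocks the segment per [segment_blocked()]. All
#' cells of the population (neurons and glia) act as obstacles.
#'
#' @param population a [cell_population()].
#' @param seed seed for resolving hits on co-located target sites.
#' @return a [connection_set()].
#' @export
rt2 <- function(population, seed = 1L) {
  rp <- .rt_prep(population)
  if (length(rp$neuron_idx) < 2L) return(connection_set())
  set.seed(derive_seed(seed, "rt2"))
  out <- .rt2_core(rp$P, rp$neuron_idx, r_n = population$r_n)
  dedup_connections(structure(out, class = c("connection_set", "data.frame")))
}

# bin lookup structure for fixed-radius queries
.radius_index <- function(P, radius) {
  b <- floor(P / radius) + 1024
  key <- (b[, 1L] * 2048 + b[, 2L]) * 2048 + b[, 3L]
  dt <- data.table::data.table(bk = key, idx = seq_len(nrow(P)))
  data.table::setkey(dt, bk)
  list(dt = dt, radius = radius)
}

.radius_query <- function(index, P, center) {
  b0 <- floor(center / index$radius) + 1024
  ks <- (( b0[1L] + .grid_offsets[, 1L]) * 2048 +
          (b0[2L] + .grid_offsets[, 2L])) * 2048 + (b0[3L] + .grid_offsets[, 3L])
  cand <- index$dt[data.table::data.table(bk = ks), on = "bk",
                   nomatch = NULL]$idx
  d2 <- (P[cand, 1L] - center[1L])^2 + (P[cand, 2L] - center[2L])^2 +
    (P[cand, 3L] - center[3L])^2
  cand[d2 <= index$radius^2]
}

#' RT-3: distance-limited connections within pivot-centered clusters
#'
#' Pivot cells are drawn uniformly without replacement from the cells not
#' yet covered by any cluster. Each pivot defines a segment of all cells
#' within `r_RT`; the all-pairs occlusion rule of [rt2()] is applied inside
#' the segment with segment members as the only obstacles. Segments are
#' traced until every neuron belongs to at least one, edge lists are pooled
#' and deduplicated, and input/output connectivity is verified. No edge
#' can be longer than `2 r_RT`.
#'
#' @param population a [cell_population()].
#' @param r_RT cluster radius in `r_n` units.
#' @param seed integer seed.
#' @param verify run [verify_io_connectivity()] and attach its report.
#' @return a [connection_set()]; attribute `io_report` when `verify`.
#' @export
rt3 <- function(population, r_RT, seed = 1L, verify = TRUE) {
  stopifnot(r_RT > 0)
  rp <- .rt_prep(population)
  P <- rp$P; M <- rp$M
  is_neuron <- population$cell_type != "glial"
  covered <- logical(M)
  idx <- .radius_index(P, r_RT)
  set.seed(derive_seed(seed, "rt3"))
  pieces <- list()
  while (any(!covered & is_neuron)) {
    uncov <- which(!covered)
    pivot <- uncov[sample.int(length(uncov), 1L)]
    members <- .radius_query(idx, P, P[pivot, ])
    covered[members] <- TRUE
    loc_neur <- which(is_neuron[members])
    if (length(loc_neur) >= 2L) {
      e <- .rt2_core(P[members, , drop = FALSE], loc_neur,
                     r_n = population$r_n)
      if (nrow(e)) {
        e$source <- members[e$source]; e$target <- members[e$target]
        pieces[[length(pieces) + 1L]] <- e
      }
    }
  }
  out <- if (length(pieces)) do.call(rbind, pieces) else
    data.frame(source = integer(0), target = integer(0), length = numeric(0))
  out <- dedup_connections(structure(out, class = c("connection_set", "data.frame")))
  if (verify) {
    cnt <- population_counts(population)
    attr(out, "io_report") <-
      verify_io_connectivity(out, cnt[["N_I"]], cnt[["N_O"]],
                             n_neurons = sum(is_neuron))
  }
  out
}

#' Verify that every input neuron reaches every output neuron
#'
#' Traverses the connection graph backward from each output neuron over
#' reversed edges and reports, per input neuron, how many outputs it can
#' reach through directed paths.
#'
#' @param conn a [connection_set()] with neuron indices 1..n_neurons,
#'   inputs first and outputs last.
#' @param N_I,N_O input and output neuron counts.
#' @param n_neurons total neuron count (defaults to the largest index
#'   present).
#' @return list with `per_input` data.frame (input, n_outputs_reachable,
#'   ok) and logical `all_connected`.
#' @export
verify_io_connectivity <- function(conn, N_I, N_O,
                                   n_neurons = max(c(conn$source, conn$target, N_I + N_O))) {
  inputs <- seq_len(N_I)
  outputs <- seq.int(n_neurons - N_O + 1L, length.out = N_O)
  if (N_I == 0L || N_O == 0L)
    return(list(per_input = data.frame(input = integer(0),
                                       n_outputs_reachable = integer(0),
                                       ok = logical(0)),
                all_connected = TRUE))
  g <- igraph::make_empty_graph(n = n_neurons, directed = TRUE)
  if (nrow(conn))
    g <- igraph::add_edges(g, rbind(conn$source, conn$target))
  reach <- matrix(FALSE, N_I, N_O)
  for (o in seq_along(outputs)) {
    anc <- as.integer(igraph::subcomponent(g, outputs[o], mode = "in"))
    reach[, o] <- inputs %in% anc
  }
  per_input <- data.frame(input = inputs,
                          n_outputs_reachable = rowSums(reach),
                          ok = rowSums(reach) == N_O)
  list(per_input = per_input, all_connected = all(per_input$ok))
}

#' Analytic probability that a segment of length r is unblocked
#'
#' In the sparse-density regime the blocking cells form a cylinder of
#' radius `r_n` along the segment, giving success probability
#' `1 - pi r_n^2 eta_T r`, clamped at zero.
#'
#' @param r segment length(s), `>= 0`.
#' @param eta_T total cell density in `r_n^-3`.
#' @param r_n cell radius.
#' @return probability in `[0, 1]`, non-increasing in `r`.
#' @export
connection_prob_unblocked <- function(r, eta_T, r_n = 1) {
  stopifnot(all(r >= 0))
  pmax(0, 1 - pi * r_n^2 * eta_T * r)
}

# unnormalized connection-length density on [0, 2 r_m]
.conn_pdf_raw <- function(r, r_m, eta_T, r_n) {
  ifelse(r < 0 | r > 2 * r_m, 0,
         r^2 * pmax(0, 1 - pi * r_n^2 * eta_T * r) *
           (r - 2 * r_m)^2 * (r + 4 * r_m))
}

#' Normalization constant of the connection-length density
#'
#' @inheritParams connection_pdf_analytic
#' @return `K` such that the density integrates to 1 over `[0, 2 r_m]`.
#'   In the zero-density limit `K = 3 / (16 r_m^6)` exactly.
#' @export
connection_pdf_const <- function(r_m, eta_T = 0, r_n = 1) {
  Z <- integrate(.conn_pdf_raw, 0, 2 * r_m, r_m = r_m, eta_T = eta_T,
                 r_n = r_n, rel.tol = 1e-12)$value
  1 / Z
}

#' Analytic probability density of ray-traced connection lengths
#'
#' For clusters of radius `r_m` in a medium of total cell density `eta_T`,
#' the length density of distance-limited ray-traced connections is
#' `K r^2 (1 - pi r_n^2 eta_T r) (r - 2 r_m)^2 (r + 4 r_m)` on
#' `[0, 2 r_m]` and zero outside, with `K` normalizing the integral to 1.
#' The expression assumes the sparse-density regime; at densities around
#' `2e-2 r_n^-3` and above it no longer matches simulation.
#'
#' @param r length(s) at which to evaluate the density.
#' @param r_m cluster radius.
#' @param eta_T total cell density in `r_n^-3` (0 gives the
#'   density-independent limit).
#' @param r_n cell radius.
#' @return density values (0 outside the support).
#' @export
connection_pdf_analytic <- function(r, r_m, eta_T = 0, r_n = 1) {
  K <- connection_pdf_const(r_m, eta_T, r_n)
  K * .conn_pdf_raw(r, r_m, eta_T, r_n)
}

#' Analytic CDF of ray-traced connection lengths
#'
#' Numerical integral of [connection_pdf_analytic()]; evaluated on a fine
#' trapezoid grid for vectorized use (e.g. KS statistics).
#'
#' @inheritParams connection_pdf_analytic
#' @param n_grid trapezoid resolution.
#' @return a function mapping lengths to cumulative probability.
#' @export
connection_cdf_analytic <- function(r_m, eta_T = 0, r_n = 1, n_grid = 4096L) {
  x <- seq(0, 2 * r_m, length.out = n_grid)
  f <- connection_pdf_analytic(x, r_m, eta_T, r_n)
  cdf <- cumsum(c(0, diff(x) * (head(f, -1) + tail(f, -1)) / 2))
  cdf <- cdf / cdf[n_grid]
  function(r) {
    r <- pmin(pmax(r, 0), 2 * r_m)
    stats::approx(x, cdf, xout = r, rule = 2)$y
  }
}

#' Out-degree statistics of a connection set
#'
#' @param population a [cell_population()] (supplies the neuron count).
#' @param conn a [connection_set()].
#' @return list with `mean_out_degree` (over all neurons, including those
#'   with no outgoing edges) and `histogram` (table of out-degrees).
#' @export
connections_per_neuron <- function(population, conn) {
  n_neur <- sum(population$cell_type != "glial")
  deg <- tabulate(conn$source, nbins = n_neur)
  list(mean_out_degree = if (n_neur) mean(deg) else 0,
       histogram = table(deg))
}
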