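# Structure-preserving transfer learning: grow the network between
# datasets (new cells, larger sphere, re-traced connections restricted to
# pairs touching a new cell) while every trained weight, bias, and
# activation row survives bit-exact; or shrink it by repeated
# probabilistic pruning.

#' Describe a network growth step
#'
#' @param N_input,N_hidden,N_glial,N_output new cell counts (each `>=` the
#'   current count; `NULL` keeps the current value).
#' @param r_s new sphere radius; `NULL` selects
#'   `max(current, min_sphere_radius(N_T, P_c_th))`.
#' @param P_c_th collision threshold used for the automatic radius.
#' @param input_mode how the grown input set is laid out: `"densify"`
#'   inserts new surface sites between the old ones (old neurons keep their
#'   exact positions), `"concat"` compresses the old neurons into one polar
#'   hemisphere with factor `kappa` and adds the new ones in the vacated
#'   band, `"none"` allows no input growth.
#' @param kappa densification factor for `"concat"`, in (0, 1].
#' @param rt_algorithm,r_RT ray tracing used for the new connections
#'   (defaults to RT-3 with the radius stored on the model, else `r_s`).
#' @param init_scale multiplier on the Xavier bound of the new entries.
#' @param seed integer seed.
#' @return a `growth_plan` list.
#' @export
growth_plan <- function(N_input = NULL, N_hidden = NULL, N_glial = NULL,
                        N_output = NULL, r_s = NULL, P_c_th = 0.01,
                        input_mode = c("densify", "concat", "none"),
                        kappa = 1, rt_algorithm = c("rt3", "rt2"),
                        r_RT = NULL, init_scale = 1, seed = 1L) {
  input_mode <- match.arg(input_mode)
  if (input_mode == "concat" && (kappa <= 0 || kappa > 1))
    stop("growth_plan: kappa must be in (0, 1]")
  structure(list(N_input = N_input, N_hidden = N_hidden, N_glial = N_glial,
                 N_output = N_output, r_s = r_s, P_c_th = P_c_th,
                 input_mode = input_mode, kappa = kappa,
                 rt_algorithm = match.arg(rt_algorithm), r_RT = r_RT,
                 init_scale = init_scale, seed = as.integer(seed)),
            class = "growth_plan")
}

# slot remap old model -> grown layout: inputs keep their slots, hidden
# slots shift by the input growth, old outputs take the leading positions
# of the new output block (so old target ordering is preserved).
.slot_map <- function(N_old, N_I_old, N_O_old, N_new, N_I_new, N_O_new) {
  map <- rep(NA_integer_, N_old)
  map[seq_len(N_I_old)] <- seq_len(N_I_old)
  old_hidden <- which(seq_len(N_old) > N_I_old &
                        seq_len(N_old) <= N_old - N_O_old)
  map[old_hidden] <- old_hidden + (N_I_new - N_I_old)
  old_out <- seq.int(N_old - N_O_old + 1L, N_old)
  map[old_out] <- seq.int(N_new - N_O_new + 1L, length.out = N_O_old)
  map
}

#' Grow a trained network to a larger geometry
#'
#' Applies a [growth_plan()]: the sphere is rescaled radially (angles
#' untouched), the input surface set is densified or migrated, new hidden
#' and glial cells are placed collision-free against all existing cells,
#' and connections are re-traced — only edges touching at least one new
#' cell are added, so every old (source, target, weight) triple survives
#' with its value bit-exact, as do old biases and activation rows. New
#' entries are Xavier-initialized with fan counts taken from the combined
#' structure. Slot capacity doubles when exceeded.
#'
#' @param model a `raynn_model`.
#' @param plan a [growth_plan()].
#' @return the grown model; attribute `slot_map` maps old slots to new
#'   slots and attribute `n_new_edges` counts the added entries.
#' @export
grow_network <- function(model, plan) {
  stopifnot(inherits(plan, "growth_plan"))
  pop <- model$population
  cnt <- population_counts(pop)
  oI <- cnt[["N_I"]]; oH <- cnt[["N_h"]]; oO <- cnt[["N_O"]]; oG <- cnt[["N_g"]]
  nI <- plan$N_input %||% oI; nH <- plan$N_hidden %||% oH
  nG <- plan$N_glial %||% oG; nO <- plan$N_output %||% oO
  if (nI < oI || nH < oH || nG < oG || nO < oO)
    stop("grow_network: plan shrinks the network; use shrink_network()")
  r_s_new <- max(plan$r_s %||% 0, pop$r_s,
                 min_sphere_radius(max(1, nH + nG), plan$P_c_th))
  no_change <- nI == oI && nH == oH && nG == oG && nO == oO &&
    r_s_new == pop$r_s
  if (no_change) {
    out <- model
    attr(out, "slot_map") <- seq_len(model$N)
    attr(out, "n_new_edges") <- 0L
    return(out)
  }
  if (nI > oI && plan$input_mode == "none")
    stop("grow_network: input growth requested with input_mode = 'none'")
  pop <- grow_sphere(pop, r_s_new)
  P <- pop$positions
  type <- pop$cell_type
  in_rows <- which(type == "input"); hid_rows <- which(type == "hidden")
  out_rows <- which(type == "output"); gli_rows <- which(type == "glial")
  P_in_old <- P[in_rows, , drop = FALSE]
  # --- input growth -------------------------------------------------------
  P_in_new <- matrix(numeric(0), 0L, 3L)
  if (nI > oI) {
    if (plan$input_mode == "concat") {
      # recover v_theta from the stored polar angles, compress old inputs
      ct <- P_in_old[, 3L] / r_s_new
      v_old <- ct / 2 + 0.5
      th_new <- migrate_inputs_concat(v_old, plan$kappa)
      ph <- atan2(P_in_old[, 2L], P_in_old[, 1L])
      P_in_old <- sph_to_cart(r_s_new, th_new, ph)
      # new inputs fill the vacated band around theta = 0:
      # v' = kappa * v of a fresh helix mapped to (1 - kappa .. 1)
      side <- ceiling(sqrt(nI - oI))
      G <- place_input_grid(side, side, r_s_new)
      vt <- (attr(G, "v_theta"))[rep(seq_len(side), each = side)]
      th <- acos(pmin(1, pmax(-1, 2 * ((plan$kappa + (1 - plan$kappa) * vt) - 0.5))))
      ph2 <- atan2(G[, 2L], G[, 1L])
      P_in_new <- sph_to_cart(r_s_new, th, ph2)[seq_len(nI - oI), , drop = FALSE]
    } else {
      # densify: old sites keep their positions; new sites are the fresh
      # helix grid minus the site nearest to each old neuron
      side <- ceiling(sqrt(nI))
      G <- place_input_grid(side, side, r_s_new)
      claimed <- integer(0)
      for (a in seq_len(nrow(P_in_old))) {
        d2 <- rowSums(sweep(G, 2L, P_in_old[a, ])^2)
        d2[claimed] <- Inf
        claimed <- c(claimed, which.min(d2))
      }
      avail <- setdiff(seq_len(nrow(G)), claimed)
      P_in_new <- G[avail[seq_len(nI - oI)], , drop = FALSE]
    }
  }
  P_in_all <- rbind(P_in_old, P_in_new)
  # --- new interior cells -------------------------------------------------
  fixed <- rbind(P_in_all, P[hid_rows, , drop = FALSE], P[gli_rows, , drop = FALSE])
  n_new_int <- (nH - oH) + (nG - oG)
  P_new_int <- if (n_new_int > 0)
    .accept_reject(n_new_int, r_s_new, pop$r_n, fixed = fixed,
                   seed = derive_seed(plan$seed, "grow"))$positions
  else matrix(numeric(0), 0L, 3L)
  P_hid_all <- rbind(P[hid_rows, , drop = FALSE],
                     P_new_int[seq_len(nH - oH), , drop = FALSE])
  P_gli_all <- rbind(P[gli_rows, , drop = FALSE],
                     P_new_int[setdiff(seq_len(n_new_int), seq_len(nH - oH)), ,
                               drop = FALSE])
  P_out_all <- matrix(0, nO, 3L)
  new_pop <- cell_population(
    rbind(P_in_all, P_hid_all, P_out_all, P_gli_all),
    c(rep("input", nI), rep("hidden", nH), rep("output", nO),
      rep("glial", nG)),
    r_s = r_s_new, r_n = pop$r_n)
  # which population neuron indices are new cells
  n_neur <- nI + nH + nO
  new_neuron <- c(seq_len(nI) > oI,
                  seq_len(nH) > oH,
                  seq_len(nO) > oO)
  # --- capacity and slot remap -------------------------------------------
  N_new <- model$N
  while (N_new <= n_neur) N_new <- N_new * 2L
  map <- .slot_map(model$N, oI, oO, N_new, nI, nO)
  map[!model$slot_active] <- NA_integer_   # padding slots carry nothing
  slot_of <- c(seq_len(nI + nH), seq.int(N_new - nO + 1L, length.out = nO))
  # --- trace connections for pairs touching a new cell --------------------
  r_RT <- plan$r_RT %||% model$r_RT %||% (2 * r_s_new)
  conn <- switch(plan$rt_algorithm,
                 rt3 = rt3(new_pop, r_RT, seed = derive_seed(plan$seed, "rt"),
                           verify = FALSE),
                 rt2 = rt2(new_pop, seed = derive_seed(plan$seed, "rt")))
  touches_new <- new_neuron[conn$source] | new_neuron[conn$target]
  conn_new <- conn[touches_new, , drop = FALSE]
  old_i <- map[model$W$i]; old_j <- map[model$W$j]
  cand_i <- slot_of[conn_new$target]; cand_j <- slot_of[conn_new$source]
  dup <- paste(cand_i, cand_j) %in% paste(old_i, old_j)
  cand_i <- cand_i[dup == FALSE]; cand_j <- cand_j[dup == FALSE]
  # Xavier bounds from the combined structure, applied to new entries only
  all_i <- c(old_i, cand_i); all_j <- c(old_j, cand_j)
  if (length(cand_i)) {
    fan_in <- tabulate(all_i, nbins = N_new)[cand_i]
    fan_out <- tabulate(all_j, nbins = N_new)[cand_j]
    set.seed(derive_seed(plan$seed, "xavier-new"))
    w_new <- runif(length(cand_i), -1, 1) *
      sqrt(6 / (fan_in + fan_out)) * plan$init_scale
  } else w_new <- numeric(0)
  W <- sparse_weights(all_i, all_j, c(model$W$x, w_new), N_new)
  W <- enforce_structural_zeros(W, nI, nO, model$allow_self_loops)
  # --- carry over biases and activation rows ------------------------------
  H <- numeric(N_new)
  C_eff <- uaf_identity_params(N_new)
  live_old <- which(!is.na(map))
  H[map[live_old]] <- model$H[live_old]
  C_eff[map[live_old], ] <- model$C_eff[live_old, , drop = FALSE]
  slot_active <- logical(N_new); slot_active[slot_of] <- TRUE
  slot_pop <- rep(NA_integer_, N_new); slot_pop[slot_of] <- seq_len(n_neur)
  # initialize the newly created trainable slots
  new_slots <- setdiff(slot_of[new_neuron], seq_len(nI))
  if (length(new_slots)) {
    set.seed(derive_seed(plan$seed, "bias-new"))
    H[new_slots] <- rnorm(length(new_slots), 0, 0.01)
    C_eff[new_slots, ] <- C_eff[new_slots, , drop = FALSE] +
      matrix(rnorm(5L * length(new_slots), 0, 0.01), length(new_slots), 5L)
  }
  out <- structure(list(population = new_pop, N = N_new, N_I = nI, N_O = nO,
                        W = W, H = H, C_eff = C_eff,
                        slot_active = slot_active, slot_pop = slot_pop,
                        k = model$k, lambda = model$lambda + 1L,
                        seed = model$seed, r_RT = r_RT,
                        allow_self_loops = model$allow_self_loops),
                   class = "raynn_model")
  attr(out, "slot_map") <- map
  attr(out, "n_new_edges") <- length(cand_i)
  out
}

#' Shrink a network by repeated probabilistic pruning
#'
#' Applies [delete_connections_probabilistic()] sweeps until the live
#' entry count is at most `target_fraction` of the starting count, then
#' removes redundant neurons. Surviving entries keep their values.
#'
#' @param model a `raynn_model`.
#' @param target_fraction target nnz fraction in (0, 1].
#' @param sweep_fraction fraction removed per sweep (default 0.05).
#' @param seed integer seed.
#' @return the shrunk model.
#' @export
shrink_network <- function(model, target_fraction, sweep_fraction = 0.05,
                           seed = 1L) {
  stopifnot(target_fraction > 0, target_fraction <= 1)
  n0 <- nnz(model$W)
  sweep <- 0L
  while (nnz(model$W) > target_fraction * n0 && nnz(model$W) > 0L) {
    sweep <- sweep + 1L
    model$W <- delete_connections_probabilistic(
      model$W, sweep_fraction,
      seed = derive_seed(seed, paste0("shrink", sweep)))$W
  }
  model$opt_state <- NULL
  delete_redundant_neurons(model)$model
}

#' Compare two models before/after a transfer step
#'
#' @param old,new `raynn_model`s; when `new` carries the `slot_map`
#'   attribute from [grow_network()] preservation is checked entry by
#'   entry, otherwise by weight-value multisets.
#' @return list with `sparsity_old`, `sparsity_new` (nnz over active
#'   neuron count squared), `preserved` (old entries present in `new`
#'   with identical value), `preserved_fraction`, and parameter counts.
#' @export
transfer_report <- function(old, new) {
  sp <- function(m) nnz(m$W) / max(1L, sum(m$slot_active))^2
  map <- attr(new, "slot_map")
  if (!is.null(map)) {
    key_new <- paste(new$W$i, new$W$j)
    idx <- match(paste(map[old$W$i], map[old$W$j]), key_new)
    preserved <- sum(!is.na(idx) & new$W$x[idx] == old$W$x)
  } else {
    preserved <- sum(!is.na(match(old$W$x, new$W$x)))
  }
  list(sparsity_old = sp(old), sparsity_new = sp(new),
       preserved = preserved,
       preserved_fraction = preserved / max(1L, nnz(old$W)),
       params_old = count_trainable_params(old),
       params_new = count_trainable_params(new))
}
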