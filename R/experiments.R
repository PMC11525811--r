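# Monte-Carlo characterization of the geometry (collision curve, radial
# density, connection-length distribution, degree sweep), synthetic
# localization data with RSSI semantics, and the end-to-end transfer demo.

#' Monte-Carlo collision probability versus cell density
#'
#' For each density, `N_T` cells are placed uniformly in the sphere of the
#' matching radius and the fraction flagged by [detect_collisions()] is
#' recorded. A least-squares line is fitted in log10-log10 space and
#' solved for the density at which the collision probability crosses
#' `P_c_th`; that threshold density is also converted to the implied
#' minimum sphere radius for `N_T` cells.
#'
#' @param N_T cells per placement.
#' @param densities vector of total densities (`r_n^-3`).
#' @param seeds integer vector; each seed re-runs the whole grid.
#' @param P_c_th threshold solved for on the fitted line.
#' @return list with `table` (density, seed, P_c), `slope`, `intercept`
#'   (log10 fit on the per-density means), `threshold_density`, and
#'   `r_s_min` implied for `N_T` cells.
#' @export
mc_collision_curve <- function(N_T, densities, seeds = 1:3, P_c_th = 0.01) {
  rows <- list()
  for (sd_ in seeds) for (eta in densities) {
    r_s <- (3 * N_T / (4 * pi * eta))^(1 / 3)
    P <- sample_hidden_positions(N_T, r_s,
                                 seed = derive_seed(sd_, paste0("mc", eta)))
    n_bad <- length(detect_collisions(P, method = "minibatch"))
    rows[[length(rows) + 1L]] <-
      data.frame(density = eta, seed = sd_, P_c = n_bad / N_T)
  }
  tab <- do.call(rbind, rows)
  agg <- stats::aggregate(P_c ~ density, tab, mean)
  agg <- agg[agg$P_c > 0, , drop = FALSE]
  fit <- lm(log10(P_c) ~ log10(density), data = agg)
  slope <- unname(coef(fit)[2L]); intercept <- unname(coef(fit)[1L])
  thr <- 10^((log10(P_c_th) - intercept) / slope)
  list(table = tab, slope = slope, intercept = intercept,
       threshold_density = thr,
       r_s_min = (3 * N_T / (4 * pi * thr))^(1 / 3))
}

#' Monte-Carlo connection-length distribution versus the closed form
#'
#' Builds populations at each density (half neurons, half glia), traces
#' RT-3 connections with cluster radius `r_RT`, and compares the pooled
#' connection lengths against the analytic density
#' [connection_pdf_analytic()] by the Kolmogorov-Smirnov distance.
#'
#' @param N_T total cells per population.
#' @param densities total densities to sweep.
#' @param r_RT cluster radius.
#' @param seeds seeds pooled per density.
#' @param interior_only when `TRUE`, only lengths from clusters whose
#'   pivot lies deeper than `r_RT` below the surface enter the comparison
#'   (the closed form assumes clusters fully inside the medium; at the
#'   radius ratios used here the truncated surface clusters shift the
#'   pooled distribution only marginally, so the faithful all-cluster
#'   accounting is the default).
#' @return data.frame with density, n_lengths, ks (one row per density);
#'   attribute `lengths` holds the pooled samples per density.
#' @export
mc_length_pdf <- function(N_T, densities, r_RT, seeds = 1L,
                          interior_only = FALSE) {
  out <- list(); samples <- list()
  for (eta in densities) {
    r_s <- (3 * N_T / (4 * pi * eta))^(1 / 3)
    lens <- numeric(0)
    for (sd_ in seeds) {
      n_h <- floor(N_T / 2)
      pop <- cell_population(
        sample_hidden_positions(N_T, r_s,
                                seed = derive_seed(sd_, paste0("len", eta))),
        c(rep("hidden", n_h), rep("glial", N_T - n_h)),
        r_s = r_s, r_n = 1)
      conn <- .rt3_lengths(pop, r_RT, seed = derive_seed(sd_, "rt"),
                           interior_only = interior_only)
      lens <- c(lens, conn)
    }
    cdf <- connection_cdf_analytic(r_RT, eta_T = eta)
    ks <- if (length(lens)) {
      e <- stats::ecdf(lens)
      x <- sort(lens)
      max(abs(e(x) - cdf(x)), abs(e(x) - length(x)^-1 - cdf(x)))
    } else NA_real_
    out[[length(out) + 1L]] <- data.frame(density = eta,
                                          n_lengths = length(lens), ks = ks)
    samples[[as.character(eta)]] <- lens
  }
  res <- do.call(rbind, out)
  attr(res, "lengths") <- samples
  res
}

# RT-3 restricted to pooled lengths; optionally keeps only clusters whose
# ball lies entirely inside the network sphere.
.rt3_lengths <- function(population, r_RT, seed = 1L, interior_only = TRUE) {
  P <- population$positions
  M <- nrow(P)
  is_neuron <- population$cell_type != "glial"
  covered <- logical(M)
  idx <- .radius_index(P, r_RT)
  set.seed(derive_seed(seed, "rt3"))
  keys <- character(0); lens <- numeric(0)
  depth_ok <- sqrt(rowSums(P^2)) <= population$r_s - r_RT
  while (any(!covered & is_neuron)) {
    uncov <- which(!covered)
    pivot <- uncov[sample.int(length(uncov), 1L)]
    members <- .radius_query(idx, P, P[pivot, ])
    covered[members] <- TRUE
    if (interior_only && !depth_ok[pivot]) next
    loc_neur <- which(is_neuron[members])
    if (length(loc_neur) < 2L) next
    e <- .rt2_core(P[members, , drop = FALSE], loc_neur,
                   r_n = population$r_n, resolve_sites = FALSE)
    if (!nrow(e)) next
    kk <- paste(members[e$source], members[e$target])
    new <- !(kk %in% keys)
    keys <- c(keys, kk[new])
    lens <- c(lens, e$length[new])
  }
  lens
}

#' Synthetic indoor-localization dataset with RSSI semantics
#'
#' Emulates Wi-Fi received-signal-strength localization data: access
#' points (APs) and devices are placed uniformly in a square arena, and
#' each AP reports `RSSI = -10 * gamma * log10(d) + offset + noise`,
#' clipped to `[-99, -1]` dBm. APs beyond the detection range report the
#' sentinel `+100` (not detected). Targets are the device coordinates.
#'
#' @param P number of access points.
#' @param n number of samples (devices).
#' @param arena side length of the square arena in meters.
#' @param sigma noise standard deviation in dB.
#' @param gamma path-loss exponent.
#' @param offset path-loss offset in dBm at 1 m.
#' @param detect_range distance (m) beyond which an AP is not detected.
#' @param seed integer seed.
#' @return list with `ap` (P x 2 AP coordinates), `rssi` (n x P matrix
#'   with +100 sentinels), `targets` (n x 2 device coordinates), and the
#'   generating parameters.
#' @export
synth_localization <- function(P, n, arena = 20, sigma = 2, gamma = 2.5,
                               offset = -30, detect_range = 14, seed = 1L) {
  stopifnot(P >= 1, n >= 1)
  set.seed(derive_seed(seed, "synthloc"))
  ap <- cbind(runif(P, 0, arena), runif(P, 0, arena))
  dev <- cbind(runif(n, 0, arena), runif(n, 0, arena))
  d <- sqrt(outer(dev[, 1L], ap[, 1L], "-")^2 +
              outer(dev[, 2L], ap[, 2L], "-")^2)
  rssi <- -10 * gamma * log10(pmax(d, 0.1)) + offset +
    matrix(rnorm(n * P, 0, sigma), n, P)
  rssi <- pmin(pmax(rssi, -99), -1)
  rssi[d > detect_range] <- 100
  list(ap = ap, rssi = rssi, targets = dev, arena = arena, sigma = sigma,
       gamma = gamma, offset = offset, detect_range = detect_range,
       seed = seed)
}

#' Standardize RSSI features for network input
#'
#' Detected values in `[-99, -1]` dBm map affinely to `[-1, 1]`; the +100
#' "not detected" sentinel maps to the neutral value 0.
#'
#' @param rssi matrix from [synth_localization()].
#' @return matrix of the same shape.
#' @export
rssi_standardize <- function(rssi) {
  out <- (rssi + 50) / 49
  out[rssi == 100] <- 0
  out
}

# fit/evaluate one model on a synthetic localization dataset
.loc_fit <- function(model, data, config, loss_target = NULL,
                     stop_at_target = FALSE, holdout = 0.25) {
  n <- nrow(data$rssi)
  n_te <- max(1L, floor(holdout * n))
  te <- seq_len(n_te); tr <- setdiff(seq_len(n), te)
  X <- t(rssi_standardize(data$rssi)) ; Y <- t(data$targets / data$arena)
  train_model(model, list(X[, tr, drop = FALSE]), list(Y[, tr, drop = FALSE]),
              config,
              val = list(inputs = list(X[, te, drop = FALSE]),
                         targets = list(Y[, te, drop = FALSE])),
              loss_target = loss_target, stop_at_target = stop_at_target)
}

#' Build a localization model for a given number of access points
#'
#' @param P input features (APs).
#' @param N_hidden,N_glial interior cell counts.
#' @param r_RT cluster radius for RT-3.
#' @param r_s requested sphere radius (the collision-safe minimum wins).
#' @param k propagation delay.
#' @param seed integer seed.
#' @return a `raynn_model` with `P` inputs and 2 outputs.
#' @export
build_localization_model <- function(P, N_hidden = 40L, N_glial = 40L,
                                     r_RT = 60, r_s = NULL, k = 2L,
                                     seed = 1L) {
  cfg <- geometry_config(N_hidden = N_hidden, N_glial = N_glial,
                         N_input = P, N_output = 2L, r_s = r_s, seed = seed)
  pop <- populate_sphere(cfg)
  conn <- rt3(pop, r_RT, seed = derive_seed(seed, "trace"), verify = FALSE)
  build_model(pop, conn, k = k, seed = seed, r_RT = r_RT)
}

#' Transfer-learning demonstration across a growing AP schedule
#'
#' Trains an initial model on a synthetic localization dataset with the
#' first AP count, then for every subsequent count grows the network with
#' [grow_network()] and retrains on the enlarged dataset. A
#' scratch-initialized control of the final geometry is trained on the
#' same data, and both are compared by the epochs needed to reach a fixed
#' training-loss threshold.
#'
#' @param schedule increasing vector of AP counts.
#' @param hidden_schedule hidden-neuron counts per stage (glia mirror it).
#' @param n samples per dataset.
#' @param epochs training epochs per stage.
#' @param lr learning rate.
#' @param r_RT cluster radius.
#' @param loss_frac threshold as a fraction of the scratch control's
#'   initial training loss.
#' @param seed integer seed.
#' @return list with per-stage records, `epochs_transfer`,
#'   `epochs_scratch` (epochs to threshold on the final stage), and the
#'   trained models.
#' @export
demo_transfer_pipeline <- function(schedule = c(6L, 8L),
                                   hidden_schedule = c(40L, 50L),
                                   n = 240L, epochs = 200L, lr = 0.01,
                                   r_RT = 60, loss_frac = 0.5, seed = 1L) {
  stopifnot(length(schedule) == length(hidden_schedule),
            all(diff(schedule) > 0))
  cfg <- train_config(optimizer = "adam", lr = lr, epochs = epochs,
                      seed = seed)
  stages <- list()
  model <- build_localization_model(schedule[1L], hidden_schedule[1L],
                                    hidden_schedule[1L], r_RT = r_RT,
                                    seed = seed)
  data <- synth_localization(schedule[1L], n, seed = derive_seed(seed, "d1"))
  fit <- .loc_fit(model, data, cfg)
  stages[[1L]] <- list(P = schedule[1L], log = fit$log,
                       params = count_trainable_params(fit$model))
  model <- fit$model
  epochs_transfer <- epochs_scratch <- NA_integer_
  for (s in seq_along(schedule)[-1L]) {
    data <- synth_localization(schedule[s], n,
                               seed = derive_seed(seed, paste0("d", s)))
    plan <- growth_plan(N_input = schedule[s],
                        N_hidden = hidden_schedule[s],
                        N_glial = hidden_schedule[s],
                        r_RT = r_RT, input_mode = "densify",
                        seed = derive_seed(seed, paste0("g", s)))
    grown <- grow_network(model, plan)
    scratch <- build_localization_model(schedule[s], hidden_schedule[s],
                                        hidden_schedule[s], r_RT = r_RT,
                                        seed = derive_seed(seed, "scratch"))
    # threshold: half of the scratch control's initial loss
    X <- t(rssi_standardize(data$rssi)); Y <- t(data$targets / data$arena)
    f0 <- forward(scratch, list(X))
    tau <- loss_frac * loss_mse(f0$outputs, list(Y))
    fit_t <- .loc_fit(grown, data, cfg, loss_target = tau)
    fit_s <- .loc_fit(scratch, data, cfg, loss_target = tau)
    epochs_transfer <- fit_t$epochs_to_target
    epochs_scratch <- fit_s$epochs_to_target
    stages[[s]] <- list(P = schedule[s], log = fit_t$log,
                        params = count_trainable_params(fit_t$model),
                        tau = tau,
                        epochs_transfer = epochs_transfer,
                        epochs_scratch = epochs_scratch)
    model <- fit_t$model
  }
  list(stages = stages, model = model,
       epochs_transfer = epochs_transfer, epochs_scratch = epochs_scratch)
}
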