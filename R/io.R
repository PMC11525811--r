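# Plain-text external interfaces: positions and connection tables
# (tab-delimited, 0-based ids), Matrix Market weights, and a model bundle
# directory with a JSON metadata file.

#' Write / read a cell positions table
#'
#' Tab-delimited columns `cell_id` (0-based, in weight-matrix index
#' order), `type`, `x`, `y`, `z` (units of `r_n`).
#'
#' @param population a [cell_population()].
#' @param path file path.
#' @export
write_positions <- function(population, path) {
  df <- data.frame(cell_id = seq_len(nrow(population$positions)) - 1L,
                   type = population$cell_type,
                   x = population$positions[, 1L],
                   y = population$positions[, 2L],
                   z = population$positions[, 3L])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_positions
#' @param r_s,r_n sphere and cell radius for the reconstructed population
#'   (`r_s` defaults to the largest radial norm in the table).
#' @export
read_positions <- function(path, r_s = NULL, r_n = 1) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  P <- as.matrix(df[, c("x", "y", "z")])
  cell_population(P, df$type,
                  r_s = r_s %||% max(sqrt(rowSums(P^2))), r_n = r_n)
}

#' Write / read a connection table
#'
#' Tab-delimited `source_id`, `target_id` (0-based neuron ids) and
#' `length_rn`.
#'
#' @param conn a [connection_set()].
#' @param path file path.
#' @export
write_connections <- function(conn, path) {
  df <- data.frame(source_id = conn$source - 1L,
                   target_id = conn$target - 1L,
                   length_rn = conn$length)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_connections
#' @export
read_connections <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  connection_set(df$source_id + 1L, df$target_id + 1L, df$length_rn)
}

#' Write / read sparse weights in Matrix Market coordinate format
#'
#' Standard 1-based MatrixMarket `real general` coordinate files; the
#' in-memory representation stays the package's row-major coordinate form.
#'
#' @param W a [sparse_weights()].
#' @param path file path (conventionally `.mtx`).
#' @export
write_weights_mtx <- function(W, path) {
  Matrix::writeMM(methods::as(.sw_matrix(W), "generalMatrix"), path)
  invisible(path)
}

#' @rdname write_weights_mtx
#' @export
read_weights_mtx <- function(path) {
  m <- methods::as(Matrix::readMM(path), "TsparseMatrix")
  sparse_weights(m@i + 1L, m@j + 1L, m@x, nrow(m))
}

#' Save / load a model bundle directory
#'
#' A bundle holds `metadata.json` (capacity, counts, delay, geometry,
#' evolution index, seed), `positions.tsv`, `weights.mtx`,
#' `neurons.tsv` (per-slot bias and activation parameters), and
#' `slots.tsv` (slot activity and population rows).
#'
#' @param model a `raynn_model`.
#' @param dir bundle directory (created if missing).
#' @export
save_model_bundle <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(N = model$N, N_I = model$N_I, N_O = model$N_O, k = model$k,
               r_s = model$population$r_s, r_n = model$population$r_n,
               lambda = model$lambda, seed = model$seed,
               r_RT = model$r_RT, allow_self_loops = model$allow_self_loops)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_positions(model$population, file.path(dir, "positions.tsv"))
  write_weights_mtx(model$W, file.path(dir, "weights.mtx"))
  act <- data.frame(cell_id = which(model$slot_active) - 1L,
                    H = model$H[model$slot_active],
                    A = model$C_eff[model$slot_active, 1L],
                    B = model$C_eff[model$slot_active, 2L],
                    C = model$C_eff[model$slot_active, 3L],
                    D = model$C_eff[model$slot_active, 4L],
                    E = model$C_eff[model$slot_active, 5L])
  utils::write.table(act, file.path(dir, "neurons.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  slots <- data.frame(slot = which(model$slot_active) - 1L,
                      pop_row = model$slot_pop[model$slot_active] - 1L)
  utils::write.table(slots, file.path(dir, "slots.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname save_model_bundle
#' @return the reconstructed `raynn_model`.
#' @export
load_model_bundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  pop <- read_positions(file.path(dir, "positions.tsv"),
                        r_s = meta$r_s, r_n = meta$r_n)
  W <- read_weights_mtx(file.path(dir, "weights.mtx"))
  act <- utils::read.table(file.path(dir, "neurons.tsv"), header = TRUE,
                           sep = "\t")
  slots <- utils::read.table(file.path(dir, "slots.tsv"), header = TRUE,
                             sep = "\t")
  N <- meta$N
  H <- numeric(N); C_eff <- uaf_identity_params(N)
  H[act$cell_id + 1L] <- act$H
  C_eff[act$cell_id + 1L, ] <- as.matrix(act[, c("A", "B", "C", "D", "E")])
  slot_active <- logical(N); slot_active[slots$slot + 1L] <- TRUE
  slot_pop <- rep(NA_integer_, N)
  slot_pop[slots$slot + 1L] <- slots$pop_row + 1L
  structure(list(population = pop, N = N, N_I = meta$N_I, N_O = meta$N_O,
                 W = W, H = H, C_eff = C_eff, slot_active = slot_active,
                 slot_pop = slot_pop, k = meta$k, lambda = meta$lambda,
                 seed = meta$seed, r_RT = meta$r_RT,
                 allow_self_loops = isTRUE(meta$allow_self_loops)),
            class = "raynn_model")
}
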