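# Cell placement in the network sphere.
#
# Conventions (used throughout the package):
#   * all lengths are in units of the cell radius r_n;
#   * spherical coordinates (r, theta, phi) with theta the polar angle
#     measured from +z and phi the azimuth from +x (right-handed);
#   * positions are stored as an M x 3 Cartesian matrix.

#' Convert spherical to Cartesian coordinates
#'
#' @param r,theta,phi radial, polar (from +z) and azimuthal coordinates.
#' @return an `length(r) x 3` matrix with columns x, y, z.
#' @export
sph_to_cart <- function(r, theta, phi) {
  cbind(x = r * sin(theta) * cos(phi),
        y = r * sin(theta) * sin(phi),
        z = r * cos(theta))
}

#' Sample uniformly distributed positions inside the network sphere
#'
#' Positions are drawn by inverse-CDF sampling: `r = R_r^(1/3) * r_s`,
#' `theta = acos(2 (R_theta - 1/2))`, `phi = 2 pi R_phi` with the three
#' `R` variates independent Uniform(0, 1). Every equal-volume element of
#' the ball then receives the same expected number of cells.
#'
#' @param n number of positions (non-negative integer).
#' @param r_s sphere radius in units of `r_n`.
#' @param seed optional integer seed; when `NULL` the current RNG state
#'   is used.
#' @return an `n x 3` Cartesian position matrix.
#' @export
sample_hidden_positions <- function(n, r_s, seed = NULL) {
  stopifnot(length(n) == 1L, n >= 0, r_s > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  if (n == 0L) return(matrix(numeric(0), 0L, 3L,
                             dimnames = list(NULL, c("x", "y", "z"))))
  r <- runif(n)^(1 / 3) * r_s
  theta <- acos(2 * (runif(n) - 0.5))
  phi <- 2 * pi * runif(n)
  sph_to_cart(r, theta, phi)
}

#' Radial population density histogram with quadratic fit
#'
#' Histograms the radial coordinate of the hidden and glial cells and fits
#' the expected quadratic shell density `n_T(r) = a r^2` by least squares.
#' For `N_T` cells uniform in a ball of radius `r_s` the coefficient is
#' `a = 3 N_T / r_s^3`.
#'
#' @param population a [cell_population()] (or a bare position matrix).
#' @param n_bins number of equal-width radial bins.
#' @return a list with `table` (data.frame of bin centers, counts and
#'   densities), the fitted coefficient `a_fit`, and the theoretical
#'   coefficient `a_theory` (`NA` when the population is a bare matrix).
#' @export
radial_density <- function(population, n_bins = 50L) {
  stopifnot(n_bins >= 1L)
  if (inherits(population, "cell_population")) {
    keep <- population$cell_type %in% c("hidden", "glial")
    P <- population$positions[keep, , drop = FALSE]
    r_s <- population$r_s
  } else {
    P <- as.matrix(population)
    r_s <- if (nrow(P)) max(sqrt(rowSums(P^2))) else NA_real_
  }
  if (nrow(P) == 0L) stop("radial_density: empty population")
  r <- sqrt(rowSums(P^2))
  breaks <- seq(0, r_s, length.out = n_bins + 1L)
  idx <- pmin(pmax(findInterval(r, breaks, rightmost.closed = TRUE), 1L), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  centers <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  dr <- diff(breaks)[1L]
  dens <- counts / dr  # cells per unit radius
  tab <- data.frame(r = centers, count = counts, density = dens)
  if (all(counts == 0L)) stop("radial_density: no cells fall in any bin")
  fit <- lm(density ~ 0 + I(r^2), data = tab)
  list(table = tab,
       a_fit = unname(coef(fit)[1L]),
       a_theory = 3 * nrow(P) / r_s^3)
}

#' Analytic cell collision probability at a given density
#'
#' For cells of radius `r_n` at total density `eta_T` (cells per `r_n^3`),
#' the probability that a newly placed cell lies within `2 r_n` of an
#' existing cell is `(32 pi / 3) eta_T r_n^3`. The linearised expression is
#' valid only for probabilities well below 1.
#'
#' @param eta_T total cell density in units of `r_n^-3`.
#' @param r_n cell radius (default 1; densities are usually already
#'   expressed in `r_n` units).
#' @return collision probability (may exceed 1 outside the sparse regime;
#'   callers should treat values near 1 as outside the model's validity).
#' @export
collision_probability_analytic <- function(eta_T, r_n = 1) {
  stopifnot(all(eta_T >= 0))
  (32 * pi / 3) * eta_T * r_n^3
}

#' Minimum sphere radius for a target collision probability
#'
#' Inverts the analytic collision rate: to keep the collision probability of
#' `N_T` cells below `P_c_th`, the sphere radius must exceed
#' `(8 N_T / P_c_th)^(1/3)` cell radii.
#'
#' @param N_T total number of cells (neurons plus glia).
#' @param P_c_th collision-probability threshold in (0, 1).
#' @return minimum radius in units of `r_n`.
#' @export
min_sphere_radius <- function(N_T, P_c_th = 0.01) {
  stopifnot(N_T >= 1, P_c_th > 0, P_c_th < 1)
  (8 * N_T / P_c_th)^(1 / 3)
}

#' Place input neurons on an ordered surface grid
#'
#' Builds equally spaced fraction vectors `v_theta[i] = (i + 1)/(N_x + 1)`
#' and `v_phi[j] = (j + 1)/(N_y + 1)` (`i`, `j` 0-based) and maps site
#' `(i, j)` to the surface point with `theta = acos(2 (v_theta[i] - 1/2))`
#' and `phi = 2 pi v_phi[j]`. Because theta is spaced uniformly in
#' `cos(theta)`, every site subtends the same solid angle and row-major
#' pixel order is preserved.
#'
#' @param N_x,N_y grid dimensions (rows map to theta, columns to phi).
#' @param r_s sphere radius.
#' @return an `(N_x * N_y) x 3` position matrix in row-major site order,
#'   with attributes `v_theta` and `v_phi` carrying the fraction vectors.
#' @export
place_input_grid <- function(N_x, N_y, r_s) {
  stopifnot(N_x >= 1, N_y >= 1, r_s > 0)
  v_theta <- (seq_len(N_x)) / (N_x + 1)
  v_phi <- (seq_len(N_y)) / (N_y + 1)
  grid <- expand.grid(j = seq_len(N_y), i = seq_len(N_x))  # row-major
  theta <- acos(2 * (v_theta[grid$i] - 0.5))
  phi <- 2 * pi * v_phi[grid$j]
  P <- sph_to_cart(r_s, theta, phi)
  attr(P, "v_theta") <- v_theta
  attr(P, "v_phi") <- v_phi
  P
}

#' Place input neurons for one-dimensional data (helix order)
#'
#' One-dimensional feature vectors are laid onto the square grid with
#' `N_x = N_y = ceiling(sqrt(N_1D))` and flattened row-major
#' ((0,0), (0,1), ..., (1,0), ...), so that neighbouring features remain
#' neighbours on the sphere surface. The first `N_1D` sites are returned.
#'
#' @param N_1D number of features.
#' @param r_s sphere radius.
#' @return an `N_1D x 3` position matrix.
#' @export
place_input_helix <- function(N_1D, r_s) {
  stopifnot(N_1D >= 1)
  side <- ceiling(sqrt(N_1D))
  P <- place_input_grid(side, side, r_s)
  P[seq_len(N_1D), , drop = FALSE]
}

#' Place stacked input channels sharing surface sites
#'
#' For channelled data (e.g. RGB images) `C` input neurons share each grid
#' site. Co-located input neurons are exempt from the minimum-separation
#' rule, and the ray-tracing stage resolves a hit on a shared site by a
#' uniform random choice among the co-located neurons.
#'
#' @param N_x,N_y grid dimensions.
#' @param C channels per site (`C >= 1`).
#' @param r_s sphere radius.
#' @return an `(N_x * N_y * C) x 3` position matrix ordered site-major
#'   (all channels of site 1, then site 2, ...), with a `site` attribute
#'   giving the site index of each neuron.
#' @export
place_input_stacked <- function(N_x, N_y, C, r_s) {
  stopifnot(C >= 1)
  G <- place_input_grid(N_x, N_y, r_s)
  idx <- rep(seq_len(nrow(G)), each = C)
  P <- G[idx, , drop = FALSE]
  attr(P, "site") <- idx
  P
}

#' Rescale a population to a larger sphere
#'
#' Every cell's radial coordinate is multiplied by `r_s_new / r_s` while its
#' polar and azimuthal angles (its unit direction vector) are untouched, so
#' pairwise angular separations are preserved exactly. Shrinking is not
#' defined and raises an error.
#'
#' @param population a [cell_population()].
#' @param r_s_new new sphere radius, `>=` the current radius.
#' @return the rescaled population.
#' @export
grow_sphere <- function(population, r_s_new) {
  stopifnot(inherits(population, "cell_population"))
  if (r_s_new < population$r_s) stop("grow_sphere: shrinking is not supported")
  scale <- r_s_new / population$r_s
  population$positions <- population$positions * scale
  population$r_s <- r_s_new
  population
}

#' Densify the input-neuron surface grid
#'
#' Recomputes the equally spaced fraction vectors at the new grid size.
#' Old input neurons keep their exact original surface positions; the new
#' grid sites host the added neurons. The returned index map matches each
#' old site to its nearest new-grid site (bookkeeping only; positions are
#' not moved).
#'
#' @param v_theta,v_phi the old fraction vectors (from [place_input_grid()]).
#' @param N_x_new,N_y_new new grid dimensions, `>=` the old ones.
#' @return list with `v_theta`, `v_phi` (new vectors) and `map_theta`,
#'   `map_phi` (nearest new index per old element).
#' @export
densify_inputs <- function(v_theta, v_phi, N_x_new, N_y_new) {
  if (N_x_new < length(v_theta) || N_y_new < length(v_phi))
    stop("densify_inputs: grid dimensions cannot shrink")
  new_theta <- seq_len(N_x_new) / (N_x_new + 1)
  new_phi <- seq_len(N_y_new) / (N_y_new + 1)
  nearest <- function(old, new) vapply(old, function(v) which.min(abs(new - v)), 1L)
  list(v_theta = new_theta, v_phi = new_phi,
       map_theta = nearest(v_theta, new_theta),
       map_phi = nearest(v_phi, new_phi))
}

#' Migrate old input neurons toward the pole for concatenated features
#'
#' When a new dataset concatenates features to the old ones, the old input
#' neurons are compressed into one polar hemisphere by recomputing
#' `theta' = acos(2 (kappa * v_theta - 1/2))` with densification factor
#' `0 < kappa <= 1`; azimuths and existing connections are retained. With
#' `kappa < 1` every recomputed angle exceeds `pi/2`, vacating the band
#' around `theta = 0` for the new input neurons.
#'
#' @param v_theta old theta fraction vector.
#' @param kappa densification factor in (0, 1].
#' @return new polar angles (radians), one per element of `v_theta`.
#' @export
migrate_inputs_concat <- function(v_theta, kappa) {
  if (kappa <= 0 || kappa > 1) stop("migrate_inputs_concat: kappa must be in (0, 1]")
  acos(pmin(1, pmax(-1, 2 * (kappa * v_theta - 0.5))))
}
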