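# Trait-structured Lotka-Volterra competition among species sharing a
# resource base.  Each species i has pre-competition birth and death
# rates c_i and d_i (intrinsic lifetime fitness R_i = c_i/d_i), a
# habitable-environment fraction h_i, and carrying capacity
# k_i = h_i - d_i/c_i before interspecific competition.  The rate
# equation is
#
#     dn_i/dt = [c_i * (h_i - sum_j alpha_ij * n_j) - d_i] * n_i
#
# with per-capita impact alpha_ij ON i FROM j, calibrated against the
# intraspecific impact alpha_ii = 1.  Competitive roles: a slow-dominant
# keystone (low R, delivers more impact than it receives), a
# fast-subdominant weed (high R, net impact received), and a
# slow-fugitive canary (low R, delivers no impact at all).

#' Species trait table
#'
#' @param c Per-capita pre-competition birth rate(s), > 0 (1/time).
#' @param d Per-capita death rate(s), >= 0 (1/time); recycled.
#' @param h Habitable-environment fraction(s) in `[0, 1]`; recycled.
#' @return A data frame of class `"species_traits"` with columns `c`,
#'   `d`, `h`, plus derived `R = c/d` (NA where `d = 0`) and carrying
#'   capacity `k = h - d/c` (may be negative: the species is unviable).
#' @examples
#' species_traits(c = c(0.20, 1.60, 0.18), d = 0.1, h = 1)
#' @export
species_traits <- function(c, d, h = 1) {
  s <- max(length(c), length(d), length(h))
  c <- rep_len(as.numeric(c), s)
  d <- rep_len(as.numeric(d), s)
  h <- rep_len(as.numeric(h), s)
  if (any(c <= 0)) stop("birth rates c must be > 0")
  if (any(d < 0)) stop("death rates d must be >= 0")
  if (any(h < 0 | h > 1)) stop("habitable fractions h must lie in [0, 1]")
  out <- data.frame(c = c, d = d, h = h,
                    R = ifelse(d > 0, c / d, NA_real_),
                    k = h - d / c)
  class(out) <- c("species_traits", "data.frame")
  out
}

#' Competition (impact) matrix
#'
#' @param alpha Square numeric matrix; `alpha[i, j]` is the per-capita
#'   impact ON species i FROM species j.  The diagonal must be exactly 1
#'   (intraspecific calibration) and all entries non-negative.
#' @return The validated matrix, of class `"competition_matrix"`.
#' @export
competition_matrix <- function(alpha) {
  alpha <- as.matrix(alpha)
  if (nrow(alpha) != ncol(alpha)) stop("alpha must be square")
  if (anyNA(alpha) || any(alpha < 0)) stop("alpha entries must be >= 0")
  if (any(diag(alpha) != 1)) stop("diagonal impacts alpha_ii must equal 1")
  structure(alpha, class = c("competition_matrix", "matrix"))
}

#' The canonical keystone / weed / canary parameterisation
#'
#' A worked three-species community used throughout the documentation and
#' tests: a slow-dominant keystone (`c = 0.20`), a fast-subdominant weed
#' (`c = 1.60`) and a slow-fugitive canary (`c = 0.18`), all with
#' `d = 0.1`, and impact rows `(1, 0.01, 0)`, `(1.5, 1, 0)`,
#' `(0.5, 0.3, 1)`.  Under community-wide habitat degradation this
#' community loses the canary first, then the keystone, with the weed
#' persisting longest.
#'
#' @param h Habitable fraction applied to all three species (default 1).
#' @return A list with elements `traits` ([species_traits()]) and
#'   `alpha` ([competition_matrix()]); species are named keystone, weed,
#'   canary.
#' @export
three_species_example <- function(h = 1) {
  traits <- species_traits(c = c(0.20, 1.60, 0.18), d = 0.1, h = h)
  rownames(traits) <- c("keystone", "weed", "canary")
  alpha <- competition_matrix(rbind(c(1.00, 0.01, 0.00),
                                    c(1.50, 1.00, 0.00),
                                    c(0.50, 0.30, 1.00)))
  dimnames(alpha) <- list(rownames(traits), rownames(traits))
  list(traits = traits, alpha = alpha)
}

#' Per-species growth rates
#'
#' Evaluates `dn_i/dt = [c_i (h_i - sum_j alpha_ij n_j) - d_i] n_i`.
#'
#' @param n Abundances as fractions of pristine capacity (>= 0).
#' @param traits A [species_traits()] table with one row per species.
#' @param alpha A [competition_matrix()] of matching dimension.
#' @return Numeric vector of rates of change (1/time).
#' @export
growth_rate <- function(n, traits, alpha) {
  n <- as.numeric(n)
  if (length(n) != nrow(traits) || nrow(alpha) != length(n))
    stop("dimension mismatch between state, traits and alpha")
  if (anyNA(n) || any(n < 0)) stop("abundances must be non-negative")
  (traits$c * (traits$h - as.vector(alpha %*% n)) - traits$d) * n
}

#' Two-species coexistence equilibrium
#'
#' Closed-form equilibrium of two competing species:
#' `n_i* = (k_i - alpha_ij k_j) / (1 - alpha_ij alpha_ji)`, clipped to 0
#' when negative (the species is excluded), and symmetrically for j.
#' When one species is excluded the other rests at its own `k` (clipped
#' at 0).
#'
#' @param traits [species_traits()] for the two species (or a larger
#'   table, with `i`, `j` selecting rows).
#' @param alpha [competition_matrix()] (full community matrix; entries
#'   `[i, j]` and `[j, i]` are used).
#' @param i,j Row indices of the two species (defaults 1 and 2).
#' @return A list with `n_star` (length-2 named vector, order `i`, `j`)
#'   and `feasible` (logical, `n_star > 0`).
#' @export
pairwise_equilibrium <- function(traits, alpha, i = 1L, j = 2L) {
  aij <- alpha[i, j]; aji <- alpha[j, i]
  den <- 1 - aij * aji
  if (abs(den) < 1e-12)
    stop("degenerate competition: alpha_ij * alpha_ji = 1 (neutral pair)")
  ki <- traits$k[i]; kj <- traits$k[j]
  ni <- (ki - aij * kj) / den
  nj <- (kj - aji * ki) / den
  # an infeasible partner leaves the survivor at its single-species k
  if (ni <= 0 && nj > 0) { ni <- 0; nj <- max(kj, 0) }
  if (nj <= 0 && ni > 0) { nj <- 0; ni <- max(ki, 0) }
  if (ni <= 0 && nj <= 0) { ni <- 0; nj <- 0 }
  n_star <- c(max(ni, 0), max(nj, 0))
  names(n_star) <- rownames(traits)[c(i, j)]
  list(n_star = n_star, feasible = n_star > 0)
}

#' Fugitive-species equilibrium among resident competitors
#'
#' A fugitive delivers no impact on the residents (`alpha[resident,
#' fugitive] = 0`), so it equilibrates on top of their equilibrium:
#' `n_3* = k_3 - alpha_31 n_1* - alpha_32 n_2*`, clipped to 0.
#'
#' @param traits [species_traits()] table containing the fugitive row.
#' @param alpha Full [competition_matrix()].
#' @param resident_eq Named or ordered abundances of the residents at
#'   equilibrium (e.g. `pairwise_equilibrium(...)$n_star`).
#' @param fugitive Row index of the fugitive species (default 3).
#' @param residents Row indices of the residents (default `c(1, 2)`).
#' @return The fugitive's equilibrium abundance (>= 0).
#' @export
fugitive_equilibrium <- function(traits, alpha, resident_eq,
                                 fugitive = 3L, residents = c(1L, 2L)) {
  if (any(alpha[residents, fugitive] != 0))
    stop("not a fugitive: it delivers nonzero impact on a resident ",
         "(alpha[resident, fugitive] must be 0)")
  if (length(resident_eq) != length(residents))
    stop("resident_eq must hold one abundance per resident")
  n3 <- traits$k[fugitive] -
    sum(alpha[fugitive, residents] * as.numeric(resident_eq))
  max(n3, 0)
}

#' Closed-form community equilibrium of the three-role structure
#'
#' Residents (all species that deliver impact on someone) equilibrate by
#' [pairwise_equilibrium()] with exclusion clipping; fugitives then sit
#' at their [fugitive_equilibrium()].  Only the two-resident plus
#' fugitives structure has a closed form here.
#'
#' @inheritParams growth_rate
#' @return Named vector of equilibrium abundances (0 = excluded).
#' @export
community_equilibrium <- function(traits, alpha) {
  S <- nrow(traits)
  delivers <- vapply(seq_len(S), function(j)
    any(alpha[-j, j] > 0), logical(1))
  res <- which(delivers); fug <- which(!delivers)
  n_star <- numeric(S)
  if (length(res) > 2L)
    stop("closed form available for at most two resident competitors")
  if (length(res) == 2L) {
    eq <- pairwise_equilibrium(traits, alpha, res[1L], res[2L])
    n_star[res] <- eq$n_star
  } else if (length(res) == 1L) {
    n_star[res] <- max(traits$k[res], 0)
  }
  for (f in fug)
    n_star[f] <- fugitive_equilibrium(traits, alpha, n_star[res],
                                      fugitive = f, residents = res)
  names(n_star) <- rownames(traits)
  n_star
}

#' Integrate the community to steady state
#'
#' Numerically integrates the rate equation with an adaptive solver until
#' the largest absolute rate falls below `tol` or the time horizon is
#' reached.  Used as the numerical oracle for the closed-form equilibria.
#'
#' @inheritParams growth_rate
#' @param n0 Initial abundances (>= 0).
#' @param horizon Maximum integration time (default 1e5).
#' @param tol Steady-state threshold on `max |dn_i/dt|` (default 1e-9).
#' @return A list with `state` (non-negative abundances), `converged`
#'   (logical), `time` (when the tolerance was met, or the horizon) and
#'   `max_rate`.  Non-convergence is flagged, never silent.
#' @export
integrate_to_steady_state <- function(n0, traits, alpha,
                                      horizon = 1e5, tol = 1e-9) {
  stopifnot(horizon > 0, tol > 0)
  n0 <- as.numeric(n0)
  if (anyNA(n0) || any(n0 < 0)) stop("initial abundances must be >= 0")
  deriv <- function(t, n, parms) {
    n <- pmax(n, 0)
    list((traits$c * (traits$h - as.vector(alpha %*% n)) - traits$d) * n)
  }
  # geometric checkpoints: dynamics at these parameter scales settle on
  # O(1/min rate) timescales, so early checkpoints catch fast systems
  times <- unique(c(0, 10^seq(0, log10(horizon), length.out = 60L)))
  sol <- deSolve::ode(y = n0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  states <- pmax(sol[, -1L, drop = FALSE], 0)
  rates <- apply(states, 1L, function(s)
    max(abs(growth_rate(s, traits, alpha))))
  hit <- which(rates < tol)
  idx <- if (length(hit)) hit[1L] else nrow(states)
  state <- states[idx, ]
  names(state) <- rownames(traits)
  list(state = state, converged = length(hit) > 0,
       time = sol[idx, 1L], max_rate = rates[idx])
}

#' Habitat-degradation extinction scan
#'
#' Applies the same habitable fraction `h` to every species (community-
#' wide degradation), computes the closed-form equilibrium along a
#' descending grid of `h`, and reports for each species the largest `h`
#' at which its equilibrium abundance first reaches zero, refined by
#' root-finding between grid points.  Species still extant at the grid
#' minimum get `NA` with status `"below grid minimum"`.
#'
#' @param traits [species_traits()] template (its `h` column is
#'   overwritten by the scan).
#' @param alpha [competition_matrix()].
#' @param h_grid Descending habitat fractions spanning `[0, 1]`.
#' @param extinct_tol Equilibrium abundance treated as extinct
#'   (default 1e-8).
#' @param h_tol Bisection tolerance on the threshold (default 1e-6).
#' @return A list with `thresholds` (data frame: species, `h_extinct`,
#'   `status`), `order` (species names, first extinction first) and
#'   `equilibria` (data frame of abundances along the grid).
#' @export
extinction_scan <- function(traits, alpha, h_grid = seq(1, 0, by = -0.002),
                            extinct_tol = 1e-8, h_tol = 1e-6) {
  h_grid <- sort(as.numeric(h_grid), decreasing = TRUE)
  if (min(h_grid) < 0 || max(h_grid) > 1) stop("h_grid must lie in [0, 1]")
  S <- nrow(traits)
  eq_at <- function(h) {
    tr <- traits; tr$h <- h; tr$k <- h - tr$d / tr$c
    community_equilibrium(tr, alpha)
  }
  grid_eq <- t(vapply(h_grid, eq_at, numeric(S)))
  nm <- rownames(traits)
  if (is.null(nm)) nm <- paste0("species_", seq_len(S))
  thresholds <- rep(NA_real_, S)
  status <- rep("below grid minimum", S)
  for (s in seq_len(S)) {
    extinct <- grid_eq[, s] <= extinct_tol
    if (extinct[1L]) { thresholds[s] <- h_grid[1L]; status[s] <- "extinct at grid maximum"; next }
    first <- which(extinct)[1L]
    if (is.na(first)) next
    lo <- h_grid[first]; hi <- h_grid[first - 1L]
    root <- uniroot(function(h) eq_at(h)[s] - extinct_tol,
                    lower = lo, upper = hi, tol = h_tol)$root
    thresholds[s] <- root
    status[s] <- "threshold found"
  }
  ord <- order(-thresholds, na.last = TRUE)
  ord <- ord[!is.na(thresholds[ord])]
  list(
    thresholds = data.frame(species = nm, h_extinct = thresholds,
                            status = status),
    order = nm[ord],
    equilibria = data.frame(h = h_grid,
                            setNames(as.data.frame(grid_eq), nm))
  )
}
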