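# Seed-deterministic synthetic fixtures: dated sediment-core community
# series with controlled disorder-biodiversity phase structure, and
# canonical incidence matrices with known temperature behaviour.
#
# The core generator uses a simple Markov-style presence model rather
# than the full agent-based simulator: a pool of frequently present
# species that are almost always recorded, and a pool of ephemerals whose
# presence alternates between ordered accumulation (sections gain
# ephemerals one by one, in a fixed nesting order) and disordered loss
# (each section keeps an independent random handful).  This reproduces,
# by construction, the timeline in which high-disorder windows end in
# species-poor sections and low-disorder windows end in species-rich
# sections (anti-phase), its reversal (in-phase), or neither (disordered).

#' Scenario configuration for the synthetic core generator
#'
#' @param n_persistent Number of frequently present species (default 8).
#' @param n_ephemeral Number of ephemeral species (default 24).
#' @param phase One of `"anti"` (biodiversity peaks coincide with low
#'   disorder; the keystone-accumulation timeline), `"in"` (peaks
#'   coincide with high disorder; the ephemeral-accumulation timeline) or
#'   `"disordered"` (independent channels).
#' @param cycle Length, in sections, of one accumulation-loss cycle
#'   (default 30: fifteen ordered sections, then fifteen disordered
#'   ones, so each 15-section incidence window sits wholly inside one
#'   phase and the windowed disorder swings with full amplitude).
#' @param accumulation Fraction of the ephemeral pool present in any one
#'   section (default 0.6); ordered phases hold the canonical first
#'   species of the pool, disordered phases a churning random subset of
#'   the same size.
#' @param turnover Per-section probability that a present ephemeral
#'   churns out of the community during disordered phases, its place
#'   taken by a uniformly random species (default 0.7): controls how
#'   fast composition flickers.
#' @param n2_floor Hill's N2 reached at the peak of a stress phase,
#'   when the bloom-forming dominant concentrates abundance most
#'   (default 2.5 effective species); this is what moves N2, while
#'   richness stays roughly constant.
#' @param noise Probability that any single presence/absence is flipped
#'   (observation noise; default 0.02).
#' @param date_model `"equal"` for constant date increments or
#'   `"compaction"` for increments that widen with depth.
#' @param date_step Nominal date increment in years (default 2).
#' @param start_year First section date (default 1850).
#' @param seed Integer seed; fully determines the generated core.
#' @return A list of class `"scenario_config"`.
#' @export
scenario_config <- function(n_persistent = 8L, n_ephemeral = 24L,
                            phase = c("anti", "in", "disordered"),
                            cycle = 30L, accumulation = 0.6,
                            turnover = 0.5, noise = 0.005, n2_floor = 2.5,
                            date_model = c("equal", "compaction"),
                            date_step = 2, start_year = 1850,
                            seed = 1L) {
  phase <- match.arg(phase)
  date_model <- match.arg(date_model)
  cfg <- list(n_persistent = as.integer(n_persistent),
              n_ephemeral = as.integer(n_ephemeral), phase = phase,
              cycle = as.integer(cycle), accumulation = accumulation,
              turnover = turnover, noise = noise, n2_floor = n2_floor,
              date_model = date_model,
              date_step = date_step, start_year = start_year,
              seed = as.integer(seed))
  if (cfg$n_persistent < 1L || cfg$n_ephemeral < 2L)
    stop("need at least one persistent and two ephemeral species")
  if (cfg$cycle < 4L) stop("cycle must cover at least 4 sections")
  if (accumulation <= 0 || accumulation > 1 || turnover <= 0 || turnover >= 1)
    stop("contradictory rates: accumulation in (0,1], turnover in (0,1)")
  if (noise < 0 || noise >= 0.5) stop("noise must be in [0, 0.5)")
  if (n2_floor <= 1) stop("n2_floor must exceed 1 effective species")
  class(cfg) <- "scenario_config"
  cfg
}

#' Generate a synthetic dated community core
#'
#' Builds a [core_series()] whose disorder-biodiversity phase relation is
#' known by construction (see [scenario_config()]).  Ordered phases
#' repeat a canonical ephemeral set (nested windows, low disorder);
#' disordered phases churn the set's identity at the same richness
#' (flickering composition, high disorder).  Biodiversity moves through
#' evenness: a bloom-forming dominant concentrates abundance in
#' proportion to the trailing fraction of disordered sections, so in
#' anti-phase mode Hill's N2 falls exactly when the windowed disorder
#' rises, in-phase mode reverses the target, and disordered mode
#' decouples the channels.
#'
#' @param cfg A [scenario_config()].
#' @param n_sections Number of sections (>= 30, i.e. two windows).
#' @return A [core_series()] with depths at 0.5 cm spacing.
#' @export
generate_core <- function(cfg, n_sections = 90L) {
  if (!inherits(cfg, "scenario_config")) stop("cfg must be a scenario_config")
  n_sections <- as.integer(n_sections)
  if (n_sections < 30L) stop("need at least 30 sections (two windows)")
  with_seed(cfg$seed, {
    np <- cfg$n_persistent; ne <- cfg$n_ephemeral
    half <- cfg$cycle %/% 2L
    pres <- matrix(0L, n_sections, np + ne)
    colnames(pres) <- c(paste0("P", seq_len(np)), paste0("E", seq_len(ne)))
    steady <- min(max(2L, round(ne * cfg$accumulation)), ne - 1L)
    eph_set <- rep(c(TRUE, FALSE), c(steady, ne - steady))
    sigma <- integer(n_sections)  # 1 = disordered (flicker) section
    for (t in seq_len(n_sections)) {
      pos <- (t - 1L) %% cfg$cycle
      calm <- pos < half
      sigma[t] <- as.integer(!calm || cfg$phase == "disordered")
      eph_set <- if (sigma[t] == 1L) {
        # disordered phase: same richness, churning identity
        churn_set(eph_set, steady, cfg$turnover)
      } else {
        # ordered phase: the fixed canonical set, so consecutive calm
        # sections repeat (perfectly nested)
        seq_len(ne) <= steady
      }
      row <- c(runif(np) < 0.98, eph_set)
      flip <- runif(np + ne) < cfg$noise
      pres[t, ] <- as.integer(xor(row, flip))
    }
    # Dominance tracks the trailing fraction of flicker sections over a
    # half-cycle memory, through a concave transform: the same windowed
    # quantity the nestedness temperature responds to, so the
    # biodiversity of a window's end section aligns with that window's
    # disorder (a bloom builds while turnover persists and fades as
    # ordered accumulation resumes).
    x <- trailing_mean(sigma, half)^0.4
    n2_ceiling <- 0.75 * (np + steady)
    n2_target <- switch(cfg$phase,
      anti = n2_ceiling - (n2_ceiling - cfg$n2_floor) * x,
      "in" = cfg$n2_floor + (n2_ceiling - cfg$n2_floor) * x,
      disordered = cfg$n2_floor +
        (n2_ceiling - cfg$n2_floor) * runif(n_sections))
    pres[, 1L] <- 1L  # the bloom-forming dominant is never absent
    # abundance weights are a species property; biodiversity is driven
    # by evenness: one persistent bloom-forming dominant concentrates
    # abundance (eutrophication style), and its weight is solved per
    # section so that Hill's N2 equals the phase-determined target,
    # without touching richness
    w_sp <- runif(np + ne, 0.8, 1.2)
    jit <- matrix(exp(rnorm(length(pres), 0, 0.05)), nrow(pres))
    w <- pres * jit * matrix(w_sp, nrow(pres), np + ne, byrow = TRUE)
    w[, 1L] <- solve_dominant_weight(w, n2_target)
    ab <- 100 * w / pmax(rowSums(w), .Machine$double.eps)
    dates <- synth_dates(n_sections, cfg)
    core_series(date = dates, abundance = ab,
                depth = 0.5 * (n_sections - seq_len(n_sections) + 1L))
  })
}

# Weight of the dominant (column 1) such that the section's Hill N2 on
# square-root abundances equals `target`.  With s1 = sqrt(w1), Q and P
# the sum and sum of squares of the other species' sqrt-weights,
# N2 = (s1 + Q)^2 / (s1^2 + P); solving for s1 is a quadratic, and the
# dominant (larger-weight) branch is taken.  Targets above a section's
# achievable maximum are met as closely as possible.
solve_dominant_weight <- function(w, target) {
  s <- sqrt(w)
  Q <- rowSums(s[, -1L, drop = FALSE])
  P <- rowSums(s[, -1L, drop = FALSE]^2)
  target <- pmax(target, 1 + 1e-6)
  a <- 1 - target  # < 0 because target > 1
  disc <- pmax(Q^2 - a * (Q^2 - target * P), 0)
  # of the two weights achieving the target, take the dominant branch
  s1 <- -(Q + sqrt(disc)) / a
  pmax(s1, 1e-8)^2
}

# Mean of the trailing `m` values (fewer at the start of the series).
trailing_mean <- function(x, m) {
  cs <- cumsum(x)
  n <- length(x)
  lag <- pmax(seq_len(n) - m, 0L)
  (cs - c(0, cs)[lag + 1L]) / pmin(seq_len(n), m)
}

# Disordered turnover: each member churns out with probability
# `churn_p` (identity randomises over time), then the set is topped up
# with, or stripped of, uniformly random species to hit `target`.
churn_set <- function(set, target, churn_p) {
  set[set] <- runif(sum(set)) >= churn_p
  target <- min(max(target, 0L), length(set))
  gap <- target - sum(set)
  if (gap > 0L) {
    absent <- which(!set)
    set[absent[sample.int(length(absent), gap)]] <- TRUE
  } else if (gap < 0L) {
    present <- which(set)
    set[present[sample.int(length(present), -gap)]] <- FALSE
  }
  set
}

synth_dates <- function(n, cfg) {
  inc <- switch(cfg$date_model,
    equal = rep(cfg$date_step, n - 1L),
    # compaction: the deepest (oldest) increments are the widest
    compaction = cfg$date_step * (1 + 2 * rev(seq_len(n - 1L)) / n))
  cfg$start_year + c(0, cumsum(inc))
}

#' Generate canonical incidence matrices
#'
#' Test fixtures with known temperature behaviour: `"nested"` builds a
#' subset chain (each row's species a superset of the next row's) at the
#' requested fill, so its temperature is exactly 0; `"random"` draws
#' i.i.d. Bernoulli(fill) cells; `"checkerboard"` builds the alternating
#' pattern, which is maximally non-nested, deterministic and
#' seed-independent.
#'
#' @param kind `"nested"`, `"random"` or `"checkerboard"`.
#' @param m,n Matrix dimensions (samples x species).
#' @param fill Target proportion of presences (ignored for
#'   checkerboard).
#' @param seed Integer seed (ignored for checkerboard).
#' @return A 0/1 matrix of class `"incidence_matrix"`.
#' @export
generate_matrix <- function(kind = c("nested", "random", "checkerboard"),
                            m, n, fill = 0.5, seed = 1L) {
  kind <- match.arg(kind)
  m <- as.integer(m); n <- as.integer(n)
  stopifnot(m >= 2L, n >= 2L)
  if (kind != "checkerboard") {
    if (!is.numeric(fill) || fill <= 0 || fill > 1)
      stop("infeasible fill: need 0 < fill <= 1")
  }
  cells <- switch(kind,
    checkerboard = outer(seq_len(m), seq_len(n),
                         function(i, j) (i + j) %% 2L),
    random = with_seed(seed, matrix(rbinom(m * n, 1L, fill), m, n)),
    nested = with_seed(seed, nested_cells(m, n, fill)))
  storage.mode(cells) <- "integer"
  rownames(cells) <- paste0("s", seq_len(m))
  colnames(cells) <- paste0("sp", seq_len(n))
  structure(cells, fill = mean(cells),
            class = c("incidence_matrix", "matrix"))
}

# Random non-increasing richness profile summing to round(fill*m*n),
# rendered as left-filled rows (a subset chain).
nested_cells <- function(m, n, fill) {
  target <- round(fill * m * n)
  if (target < 1L) stop("infeasible fill: no presences")
  w <- sort(rexp(m) + 0.15, decreasing = TRUE)
  r <- round(w / sum(w) * target)
  r <- pmin(pmax(r, 0L), n)
  for (k in 1:(10 * m)) {
    delta <- target - sum(r)
    if (delta == 0L) break
    if (delta > 0L) {
      i <- which(r < n)[1L]  # top up the richest row that has room
      if (is.na(i)) stop("infeasible fill for a ", m, " x ", n, " matrix")
      r[i] <- r[i] + 1L
    } else {
      i <- max(which(r > 0L))
      r[i] <- r[i] - 1L
    }
    r <- sort(r, decreasing = TRUE)
  }
  t(vapply(r, function(ri) c(rep(1L, ri), rep(0L, n - ri)), integer(n)))
}

#' Re-map core dates by a monotone compaction-like transformation
#'
#' Emulates sediment compaction: section dates are stretched so that
#' older sections are more widely spaced in time, while abundances (and
#' depths) are untouched.  Because every correlation in the signal module
#' uses only section order, its outputs are exactly invariant under this
#' re-dating.
#'
#' @param core A [core_series()].
#' @param mode `"compaction"` applies the nonlinear stretch;
#'   `"identity"` returns the core unchanged.
#' @param strength Exponent of the stretch (> 1 widens old increments;
#'   values <= 0 produce a non-monotone or reversed mapping and are
#'   rejected).
#' @return A [core_series()] with re-mapped dates.
#' @export
perturb_dates <- function(core, mode = c("compaction", "identity"),
                          strength = 2) {
  core <- as_core_series(core)
  mode <- match.arg(mode)
  if (mode == "identity") return(core)
  last <- max(core$date)
  span <- last - min(core$date)
  age <- (last - core$date) / span
  new_dates <- last - span * age^strength
  if (any(diff(new_dates) <= 0))
    stop("non-monotone date mapping rejected (strength must be > 0)")
  core_series(date = new_dates, abundance = core$abundance,
              depth = core$depth)
}

# Evaluate expr with a deterministic RNG state, restoring the caller's.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
  }
  expr
}
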