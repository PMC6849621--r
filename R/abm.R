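# Stochastic agent-based simulation of an open community of canary,
# keystone and weedy species under community-wide death-rate forcing.
#
# Discrete-time stochastic rendering of the rate equation: in a timestep
# of length dt each individual of species i dies with probability
# dt * d(t) and each survivor reproduces with probability
# dt * c_i * max(0, h - sum_j alpha_ij * ntilde_j), where ntilde_j is
# species j's abundance as a fraction of the community capacity.  The
# expected per-capita change therefore matches the deterministic rate
# equation to first order in dt.  Impacts are generated from a
# category-pair base table scaled by per-species competitive multipliers,
# with canaries delivering no impact on anyone (fugitive traits).

#' Trait regions of the three functional categories
#'
#' Base parameterisation from which [draw_species()] samples.  Rates are
#' per unit time (converted to per-step probabilities by `dt`).  The
#' impact base table rows are receivers, columns deliverers; the canary
#' column is identically zero (fugitives deliver no impact).  Keystones
#' combine low intrinsic fitness R = c/d with positive net dominance
#' (delivered minus received impact); weeds have high R and negative
#' dominance; canaries have low R, no delivered impact.
#'
#' @param c_canary,c_keystone,c_weed Birth-rate ranges per category.
#' @param mult_range Range of the per-species competitive multipliers
#'   applied to delivered and received impacts.
#' @return A list of class `"trait_regions"` with the rate ranges and
#'   the `base` impact table.
#' @export
trait_regions <- function(c_canary = c(0.10, 0.13),
                          c_keystone = c(0.16, 0.24),
                          c_weed = c(1.2, 2.0),
                          mult_range = c(0.9, 1.1)) {
  base <- rbind(keystone = c(keystone = 0.7, weed = 0.01, canary = 0),
                weed     = c(keystone = 1.5, weed = 0.7,  canary = 0),
                canary   = c(keystone = 0.5, weed = 0.3,  canary = 0))
  ranges <- list(canary = sort(c_canary), keystone = sort(c_keystone),
                 weed = sort(c_weed))
  if (any(vapply(ranges, function(r) any(r <= 0), logical(1))))
    stop("contradictory region: birth rates must be positive")
  if (max(ranges$canary) >= min(ranges$weed) ||
      max(ranges$keystone) >= min(ranges$weed))
    stop("contradictory regions: weeds must be the fast category")
  structure(list(base = base, c_range = ranges,
                 mult_range = sort(mult_range)),
            class = "trait_regions")
}

#' Draw one species from a trait region
#'
#' Samples a birth rate uniformly from the category's range and
#' competitive multipliers from `mult_range`.  Impacts against any
#' resident follow the base table scaled by the two species'
#' multipliers, so a canary always delivers exactly zero impact.
#'
#' @param category `"canary"`, `"keystone"` or `"weed"`.
#' @param regions A [trait_regions()] object.
#' @return A one-row data frame: `category`, `c`, `deliver_mult`,
#'   `receive_mult`.
#' @export
draw_species <- function(category = c("canary", "keystone", "weed"),
                         regions = trait_regions()) {
  category <- match.arg(category)
  rng <- regions$c_range[[category]]
  data.frame(category = category,
             c = runif(1L, rng[1L], rng[2L]),
             deliver_mult = if (category == "canary") 0
                            else runif(1L, regions$mult_range[1L],
                                       regions$mult_range[2L]),
             receive_mult = runif(1L, regions$mult_range[1L],
                                  regions$mult_range[2L]))
}

#' Death-rate forcing schedule
#'
#' Three consecutive periods: constant baseline death rate; the same
#' mean with a square-wave toggle; and a toggling, linearly rising mean
#' (the intensified forcing that precipitates keystone collapse).
#'
#' @param periods Length, in timesteps, of the three periods.
#' @param d0 Baseline death rate (1/time).
#' @param toggle_amp Amplitude of the square-wave toggle around the
#'   mean.
#' @param toggle_half Half-period of the toggle, in timesteps; the
#'   default matches the span of one 15-census disorder window, so the
#'   windowed disorder responds to the toggle without lag.
#' @param rise_to Mean death rate reached at the end of period 3.
#' @param toggle_mode `"deterministic"` (square wave) or `"stochastic"`
#'   (the sign of each half-period block is drawn at random).
#' @return A list of class `"forcing_schedule"` with a `d_at(t, signs)`
#'   closure evaluated by the simulator.
#' @export
forcing_schedule <- function(periods = c(240L, 360L, 360L), d0 = 0.10,
                             toggle_amp = 0.06, toggle_half = 90L,
                             rise_to = 0.45,
                             toggle_mode = c("deterministic", "stochastic")) {
  toggle_mode <- match.arg(toggle_mode)
  periods <- as.integer(periods)
  stopifnot(length(periods) == 3L, all(periods > 0L), d0 > 0,
            toggle_amp >= 0, toggle_half >= 1L, rise_to >= d0)
  structure(list(periods = periods, d0 = d0, toggle_amp = toggle_amp,
                 toggle_half = as.integer(toggle_half), rise_to = rise_to,
                 toggle_mode = toggle_mode, total = sum(periods)),
            class = "forcing_schedule")
}

#' Death rate at a given timestep
#'
#' @param schedule A [forcing_schedule()].
#' @param t Timestep (1-based), within the schedule.
#' @param signs Optional pre-drawn block signs for stochastic toggling
#'   (from the simulator).
#' @return The community-wide death rate d(t).
#' @export
forcing_at <- function(schedule, t, signs = NULL) {
  p <- schedule$periods
  if (t < 1L || t > schedule$total) stop("t outside the schedule")
  period <- findInterval(t, cumsum(p), left.open = TRUE) + 1L
  if (period == 1L) return(schedule$d0)
  block <- ((t - p[1L] - 1L) %/% schedule$toggle_half)
  sq <- if (schedule$toggle_mode == "deterministic") {
    if (block %% 2L == 0L) 1 else -1
  } else {
    if (is.null(signs)) stop("stochastic toggling needs pre-drawn signs")
    signs[block + 1L]
  }
  mean_d <- if (period == 2L) schedule$d0
            else schedule$d0 + (schedule$rise_to - schedule$d0) *
                   (t - p[1L] - p[2L]) / p[3L]
  max(mean_d + schedule$toggle_amp * sq, 0)
}

#' Simulation configuration
#'
#' @param init_species Named integer vector: initial species per
#'   category.
#' @param capacity Community capacity, in individuals, against which
#'   fractional abundances are measured.
#' @param init_frac Initial abundance of each founder species as a
#'   fraction of capacity.
#' @param invasion_p Probability per timestep that a new species enters
#'   the open community.
#' @param invasion_weights Category probabilities for invaders (default
#'   uniform; canaries' rapid extinction emerges rather than being
#'   imposed).
#' @param invader_n Individuals per invading species.
#' @param dt Timestep length (time units); per-step probabilities are
#'   `dt` times the rates, so keep `dt * rates` well below 1.
#' @param h Habitable-environment fraction (default 1).
#' @param burn_in Equilibration steps at the baseline death rate before
#'   the schedule starts; censuses begin after burn-in, so the founder
#'   transient does not contaminate period 1.
#' @param census_every Record a community census every this many steps.
#' @param window Censuses per incidence window for the internal
#'   disorder series (default 15).
#' @param replicates Replicate communities (default 15; at least 2 for
#'   confidence intervals).
#' @param seed Integer seed; fully determines the run.
#' @param regions A [trait_regions()] object.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(init_species = c(canary = 3L, keystone = 6L, weed = 4L),
                       capacity = 600L, init_frac = 0.04,
                       invasion_p = 1.0,
                       invasion_weights = c(canary = 1, keystone = 1, weed = 1),
                       invader_n = 6L, dt = 0.5, h = 1,
                       burn_in = 150L, census_every = 6L, window = 15L,
                       replicates = 15L, seed = 1L,
                       regions = trait_regions()) {
  cfg <- list(init_species = init_species, capacity = as.integer(capacity),
              init_frac = init_frac, invasion_p = invasion_p,
              invasion_weights = invasion_weights,
              invader_n = as.integer(invader_n), dt = dt, h = h,
              burn_in = as.integer(burn_in),
              census_every = as.integer(census_every),
              window = as.integer(window),
              replicates = as.integer(replicates), seed = as.integer(seed),
              regions = regions)
  stopifnot(all(c("canary", "keystone", "weed") %in% names(init_species)),
            cfg$replicates >= 2L, cfg$capacity >= 100L,
            cfg$invasion_p >= 0, cfg$invasion_p <= 1, cfg$dt > 0)
  class(cfg) <- "sim_config"
  cfg
}

# One stochastic timestep.  `com` holds parallel vectors over species:
# category (factor levels canary/keystone/weed), c, deliver_mult,
# receive_mult, N.  Returns the updated community (extinct species are
# retained with N = 0 so censuses keep stable species identities; they
# contribute nothing to competition).
#' Advance a community by one stochastic timestep
#'
#' @param com Community list (vectors `category`, `c`, `deliver_mult`,
#'   `receive_mult`, `N`, `id`).
#' @param d_t Death rate at this step (from [forcing_at()]).
#' @param cfg A [sim_config()].
#' @return The updated community.
#' @export
abm_step <- function(com, d_t, cfg) {
  alive <- com$N > 0L
  if (!any(alive)) return(com)
  ntilde <- com$N / cfg$capacity
  base <- cfg$regions$base
  M <- base[com$category, com$category, drop = FALSE] *
    outer(com$receive_mult, com$deliver_mult)
  diag(M) <- 1
  comp <- as.vector(M %*% ntilde)
  birth_p <- pmin(1, cfg$dt * com$c * pmax(0, cfg$h - comp))
  death_p <- min(1, cfg$dt * d_t)
  surv <- rbinom(length(com$N), com$N, 1 - death_p)
  births <- rbinom(length(com$N), surv, birth_p)
  com$N <- surv + births
  com
}

new_community <- function(cfg) {
  cats <- rep(c("canary", "keystone", "weed"),
              times = cfg$init_species[c("canary", "keystone", "weed")])
  rows <- lapply(cats, draw_species, regions = cfg$regions)
  tab <- do.call(rbind, rows)
  list(category = tab$category, c = tab$c,
       deliver_mult = tab$deliver_mult, receive_mult = tab$receive_mult,
       N = rep(as.integer(round(cfg$init_frac * cfg$capacity)),
               length(cats)),
       id = paste0(substr(cats, 1, 1), seq_along(cats)),
       next_id = length(cats))
}

add_invader <- function(com, cfg) {
  cat_new <- sample(names(cfg$invasion_weights), 1L,
                    prob = cfg$invasion_weights)
  sp <- draw_species(cat_new, cfg$regions)
  com$next_id <- com$next_id + 1L
  com$category <- c(com$category, sp$category)
  com$c <- c(com$c, sp$c)
  com$deliver_mult <- c(com$deliver_mult, sp$deliver_mult)
  com$receive_mult <- c(com$receive_mult, sp$receive_mult)
  com$N <- c(com$N, cfg$invader_n)
  com$id <- c(com$id, paste0(substr(cat_new, 1, 1), com$next_id))
  com
}

# Drop extinct species; their identities are never reused.
prune_extinct <- function(com) {
  keep <- com$N > 0L
  if (all(keep)) return(com)
  for (f in c("category", "c", "deliver_mult", "receive_mult", "N", "id"))
    com[[f]] <- com[[f]][keep]
  com
}

#' Run the forced-community simulation
#'
#' Simulates `replicates` independent communities through the three
#' forcing periods, records censuses, computes each replicate's sliding-
#' window disorder series and same-census Hill's N2, and reports the
#' per-period Pearson correlation of their first differences, aggregated
#' across replicates with Student-t 95% confidence intervals.
#'
#' @param cfg A [sim_config()].
#' @param schedule A [forcing_schedule()].
#' @return A list of class `"sim_output"`: `series` (long data frame:
#'   timestep, replicate, category, species_count, individual_count),
#'   `correlations` (replicate, period, r, p, n), `summary` (period,
#'   mean_r, ci_lo, ci_hi, n_replicates), `collapsed` (TRUE when every
#'   replicate ended empty), plus the `config` and `schedule`.
#' @export
run_simulation <- function(cfg = sim_config(), schedule = forcing_schedule()) {
  reps <- lapply(seq_len(cfg$replicates), function(r)
    with_seed(cfg$seed + 7919L * r, run_one(cfg, schedule, r)))
  series <- do.call(rbind, lapply(reps, `[[`, "series"))
  correlations <- do.call(rbind, lapply(reps, `[[`, "correlations"))
  by_period <- split(correlations$r, correlations$period)
  n_eff <- vapply(by_period, function(v) sum(!is.na(v)), integer(1))
  mean_r <- vapply(by_period, function(v) mean(v, na.rm = TRUE), numeric(1))
  half <- vapply(by_period, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) return(NA_real_)
    qt(0.975, length(v) - 1L) * sd(v) / sqrt(length(v))
  }, numeric(1))
  summary <- data.frame(period = as.integer(names(by_period)),
                        mean_r = mean_r, ci_lo = mean_r - half,
                        ci_hi = mean_r + half, n_replicates = n_eff)
  rownames(summary) <- NULL
  out <- list(series = series, correlations = correlations,
              summary = summary,
              collapsed = all(vapply(reps, `[[`, logical(1), "collapsed")),
              config = cfg, schedule = schedule)
  class(out) <- "sim_output"
  out
}

#' @export
print.sim_output <- function(x, ...) {
  cat("Forced-community simulation: ", x$config$replicates,
      " replicates, ", x$schedule$total, " steps\n", sep = "")
  cat("disorder-N2 correlation by period (mean [95% CI]):\n")
  with(x$summary, for (i in seq_along(period))
    cat(sprintf("  period %d: %+.3f [%+.3f, %+.3f]\n",
                period[i], mean_r[i], ci_lo[i], ci_hi[i])))
  if (x$collapsed) cat("  ** all replicates collapsed to empty **\n")
  invisible(x)
}

run_one <- function(cfg, schedule, rep_id) {
  com <- new_community(cfg)
  n_blocks <- ceiling((schedule$periods[2L] + schedule$periods[3L]) /
                        schedule$toggle_half) + 1L
  signs <- if (schedule$toggle_mode == "stochastic")
    sample(c(-1, 1), n_blocks, replace = TRUE) else NULL
  census_steps <- seq.int(cfg$census_every, schedule$total,
                          by = cfg$census_every)
  ab_rows <- vector("list", length(census_steps))
  cat_rows <- vector("list", length(census_steps))
  ci <- 0L
  for (t in seq_len(cfg$burn_in)) {
    if (runif(1L) < cfg$invasion_p) com <- add_invader(com, cfg)
    com <- prune_extinct(abm_step(com, schedule$d0, cfg))
  }
  for (t in seq_len(schedule$total)) {
    if (runif(1L) < cfg$invasion_p) com <- add_invader(com, cfg)
    com <- prune_extinct(abm_step(com, forcing_at(schedule, t, signs), cfg))
    if (ci < length(census_steps) && t == census_steps[ci + 1L]) {
      ci <- ci + 1L
      ab_rows[[ci]] <- setNames(com$N, com$id)
      counts <- table(factor(com$category[com$N > 0L],
                             levels = c("canary", "keystone", "weed")))
      inds <- vapply(split(com$N, factor(com$category,
                                         levels = c("canary", "keystone", "weed"))),
                     sum, numeric(1))
      cat_rows[[ci]] <- data.frame(
        timestep = t, replicate = rep_id,
        category = names(counts),
        species_count = as.integer(counts),
        individual_count = as.integer(inds))
      if (ci == length(census_steps)) break
    }
  }
  series <- do.call(rbind, cat_rows)
  rownames(series) <- NULL
  correlations <- census_correlations(ab_rows, census_steps, cfg, schedule,
                                      rep_id)
  list(series = series, correlations = correlations,
       collapsed = sum(com$N) == 0L)
}

# Per-period correlation of first differences of the windowed disorder
# series with same-census N2.
census_correlations <- function(ab_rows, census_steps, cfg, schedule,
                                rep_id) {
  ids <- unique(unlist(lapply(ab_rows, names)))
  ab <- matrix(0, length(ab_rows), length(ids),
               dimnames = list(NULL, ids))
  for (i in seq_along(ab_rows)) ab[i, names(ab_rows[[i]])] <- ab_rows[[i]]
  tot <- rowSums(ab)
  pct <- 100 * ab / pmax(tot, 1)
  core <- core_series(date = as.numeric(census_steps), abundance = pct)
  empty <- tot == 0
  rows <- lapply(1:3, function(p) data.frame(
    replicate = rep_id, period = p, r = NA_real_, p = NA_real_,
    n = 0L))
  if (sum(!empty) >= 2L * cfg$window && !any(empty)) {
    dis <- disorder_series(core, window = cfg$window)
    div <- core_diversity(core)
    paired <- pair_series(dis, div)
    diffs <- first_differences(paired)
    bounds <- cumsum(schedule$periods)
    # a diff belongs to the period containing the later census of its pair
    later <- paired$date[-1L]
    period <- findInterval(later, bounds, left.open = TRUE) + 1L
    rows <- lapply(1:3, function(p) {
      sel <- period == p & !is.na(diffs$d_n2)
      cc <- if (sum(sel) >= 3L)
        pearson_with_p(diffs$d_temperature[sel], diffs$d_n2[sel])
      else list(r = NA_real_, p = NA_real_, n = sum(sel))
      data.frame(replicate = rep_id, period = p, r = cc$r, p = cc$p,
                 n = cc$n)
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
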