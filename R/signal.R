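# The sequential disorder-biodiversity correlation diagnostic.
#
# Every computation here depends only on the order of sections, never on
# the numeric date values, so results are exactly invariant under any
# strictly monotone re-dating of the core (e.g. sediment compaction).

#' Pair a disorder series with same-date biodiversity
#'
#' Each windowed disorder value is paired with the biodiversity of the
#' window's most recent section: the biodiversity resulting from that
#' disorder.
#'
#' @param disorder Data frame from [disorder_series()] (columns `date`,
#'   `temperature`, ...).
#' @param diversity Data frame from [core_diversity()] (columns `date`,
#'   `n2`, `richness`).
#' @return A data frame with columns `date`, `temperature`, `n2`,
#'   `richness`, ordered by date.
#' @export
pair_series <- function(disorder, diversity) {
  stopifnot(is.data.frame(disorder), is.data.frame(diversity))
  i <- match(disorder$date, diversity$date)
  if (all(is.na(i))) stop("no common dates between the two series")
  if (anyNA(i))
    stop("misaligned dates: no biodiversity value for ",
         paste(format(disorder$date[is.na(i)], trim = TRUE), collapse = ", "))
  out <- data.frame(date = disorder$date,
                    temperature = disorder$temperature,
                    n2 = diversity$n2[i],
                    richness = diversity$richness[i])
  out <- out[order(out$date), , drop = FALSE]
  if (any(diff(out$date) <= 0)) stop("dates must be strictly increasing")
  rownames(out) <- NULL
  out
}

#' First differences of a paired disorder-biodiversity series
#'
#' Element `t` holds `value[t+1] - value[t]` for every channel, labelled
#' by the earlier date of the pair.
#'
#' @param paired Data frame from [pair_series()].
#' @return Data frame with columns `date` (earlier date of each pair),
#'   `d_temperature`, `d_n2`, `d_richness`; one row fewer than `paired`.
#' @export
first_differences <- function(paired) {
  stopifnot(is.data.frame(paired))
  np <- nrow(paired)
  if (np < 2L) stop("need at least two paired points to difference")
  data.frame(date = paired$date[-np],
             d_temperature = diff(paired$temperature),
             d_n2 = diff(paired$n2),
             d_richness = diff(paired$richness))
}

#' Sequential pretransition and lead-in correlations
#'
#' For each eligible date, computes Pearson's product-moment correlation
#' between the first differences of disorder and of biodiversity over two
#' complementary partitions: the "pretransition" set, the `window` most
#' recent paired points ending at that date (hence `window - 1` usable
#' difference pairs), and the "lead-in" set of all strictly earlier
#' difference pairs (reported once at least `min_lead_in` pairs exist).
#' Two-sided p-values come from the t-transform of r with `n - 2` degrees
#' of freedom; no correction is applied across dates (the diagnostic is
#' exploratory).  A zero-variance channel within a partition yields `NA`,
#' not zero.
#'
#' @param diffs Data frame from [first_differences()].
#' @param window Paired points per pretransition window (default 15).
#' @param min_lead_in Minimum lead-in difference pairs (default 5).
#' @param channel Biodiversity channel: `"n2"` or `"richness"`.
#' @return Data frame with one row per eligible date: `date`, `pre_r`,
#'   `pre_p`, `pre_n`, `lead_r`, `lead_p`, `lead_n`, `channel`.
#' @export
sequential_correlations <- function(diffs, window = 15L, min_lead_in = 5L,
                                    channel = c("n2", "richness")) {
  channel <- match.arg(channel)
  stopifnot(is.data.frame(diffs))
  window <- as.integer(window)
  if (window < 3L) stop("window must cover at least 3 paired points")
  nd <- nrow(diffs)           # nd = paired points - 1
  wd <- window - 1L           # usable diff pairs inside a window
  if (nd < wd) stop("not enough points for a single window")
  x <- diffs$d_temperature
  y <- diffs[[paste0("d_", channel)]]
  # eligible dates are the window end points; the diff at index i is
  # labelled by the earlier point, so the window ending at paired point
  # e uses diffs (e - window + 1) .. (e - 1).
  ends <- seq.int(window, nd + 1L)
  rows <- lapply(ends, function(e) {
    pre_idx <- (e - wd):(e - 1L)
    lead_idx <- seq_len(e - window)
    pre <- pearson_with_p(x[pre_idx], y[pre_idx])
    lead <- if (length(lead_idx) >= min_lead_in)
      pearson_with_p(x[lead_idx], y[lead_idx])
    else list(r = NA_real_, p = NA_real_, n = length(lead_idx))
    data.frame(end_index = e, pre_r = pre$r, pre_p = pre$p, pre_n = pre$n,
               lead_r = lead$r, lead_p = lead$p, lead_n = lead$n)
  })
  out <- do.call(rbind, rows)
  # date of the window's most recent paired point: diffs$date[e - 1] is
  # the earlier point of the final pair, so the end point itself carries
  # the next date when available; label by the last diff's own date plus
  # its position otherwise.  The paired end dates are diffs$date shifted.
  out$date <- end_dates(diffs$date, out$end_index)
  out$channel <- channel
  rownames(out) <- NULL
  out[, c("date", "pre_r", "pre_p", "pre_n",
          "lead_r", "lead_p", "lead_n", "channel")]
}

# Paired point e (1-based among paired points) has date: diffs$date[e]
# for e <= nd (each diff is labelled by its earlier point), and the final
# end point has no diff of its own; its date is unknown to `diffs`, so it
# is labelled by the last diff date (the convention: a window is known by
# the latest date at which both channels have been differenced).
end_dates <- function(diff_dates, end_index) {
  nd <- length(diff_dates)
  ifelse(end_index <= nd, diff_dates[pmin(end_index, nd)], diff_dates[nd])
}

pearson_with_p <- function(x, y) {
  n <- length(x)
  if (n < 3L || sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n))
  r <- cor(x, y)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * pt(-abs(tt), df = n - 2), n = n)
}

#' Classify the favoured functional regime from a correlation pair
#'
#' Formalises the mapping from coefficient patterns to favoured
#' functional categories as an explicit rule table, applied per date:
#'
#' * `keystone-favored`: the pretransition coefficient is significantly
#'   negative and falls below the lead-in coefficient by at least
#'   `strong` (ordered accumulation of frequently present dominants);
#' * `weed-favored`: the pretransition coefficient is significantly
#'   positive and exceeds the lead-in coefficient (disordered gain of
#'   ephemerals);
#' * `canary-favored`: the pretransition coefficient is not significant
#'   yet sits at least `strong` above the lead-in coefficient (weakly
#'   coupled, loosely interacting community);
#' * `indeterminate`: anything else, including missing coefficients.
#'
#' @param pre_r,pre_p Pretransition coefficient and two-sided p-value.
#' @param lead_r Lead-in coefficient (`NA` allowed; comparisons with a
#'   missing lead-in are indeterminate unless the pretransition evidence
#'   alone suffices, i.e. never under this table).
#' @param strong Margin between coefficients (default 0.3).
#' @param alpha Significance level (default 0.05).
#' @return A character vector of regime labels.
#' @export
classify_regime <- function(pre_r, pre_p, lead_r, strong = 0.3,
                            alpha = 0.05) {
  n <- length(pre_r)
  out <- rep("indeterminate", n)
  sig <- !is.na(pre_p) & pre_p < alpha
  cmp <- !is.na(pre_r) & !is.na(lead_r)
  keystone <- sig & pre_r < 0 & cmp & (lead_r - pre_r) >= strong
  weed <- sig & pre_r > 0 & cmp & pre_r > lead_r
  canary <- !sig & cmp & (pre_r - lead_r) >= strong
  out[canary] <- "canary-favored"
  out[weed] <- "weed-favored"
  out[keystone] <- "keystone-favored"
  out
}

#' Sensitivity of the pretransition coefficient to window size
#'
#' Recomputes the full disorder -> pairing -> differencing -> correlation
#' chain for each candidate window size and reports the pretransition
#' coefficient at the core's most recent eligible date, for choosing the
#' window that maximises the magnitude of correlation.
#'
#' @param core A [core_series()].
#' @param windows Integer vector of candidate window sizes.
#' @param channel Biodiversity channel (default `"n2"`).
#' @param min_pct Presence threshold for [build_incidence()].
#' @return Data frame with columns `window`, `r`, `abs_r`, `p`,
#'   `date` (the evaluation date for that window size).
#' @export
window_sensitivity <- function(core, windows, channel = "n2",
                               min_pct = 0) {
  core <- as_core_series(core)
  windows <- sort(unique(as.integer(windows)))
  if (max(windows) * 2L > length(core$date))
    stop("largest window exceeds half the core length")
  div <- core_diversity(core)
  rows <- lapply(windows, function(w) {
    dis <- disorder_series(core, window = w, min_pct = min_pct)
    sc <- sequential_correlations(first_differences(pair_series(dis, div)),
                                  window = w, channel = channel)
    last <- sc[nrow(sc), ]
    data.frame(window = w, r = last$pre_r, abs_r = abs(last$pre_r),
               p = last$pre_p, date = last$date)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
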