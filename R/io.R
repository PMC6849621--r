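# Core-series container and CSV exchange format.
#
# On disk a core is a plain CSV: first column the section date (numeric
# year or ISO date), an optional "depth_cm" column, and one column per
# species holding percentage abundances.  Internally dates are decimal
# years, sections are ordered oldest first (most recent last), and all
# reports use 1-based section indices.

#' Construct a dated community time series
#'
#' @param date Numeric vector of section dates (decimal years), strictly
#'   increasing; or ISO date strings, which are converted.
#' @param abundance Numeric matrix of percentage abundances, one row per
#'   section (same order as `date`), one named column per species.
#' @param depth Optional numeric vector of section depths (cm), strictly
#'   decreasing towards the most recent section.
#' @return An object of class `"core_series"`: a list with elements
#'   `date`, `abundance` and `depth` (possibly `NULL`).
#' @export
core_series <- function(date, abundance, depth = NULL) {
  date <- parse_dates(date)
  if (!is.matrix(abundance)) abundance <- as.matrix(abundance)
  storage.mode(abundance) <- "double"
  if (nrow(abundance) != length(date))
    stop("abundance must have one row per date")
  if (is.null(colnames(abundance)))
    colnames(abundance) <- paste0("sp", seq_len(ncol(abundance)))
  if (anyNA(abundance) || any(abundance < 0))
    stop("abundances must be non-negative and complete")
  if (anyNA(date)) stop("dates must parse as numeric years or ISO dates")
  dup <- date[duplicated(date)]
  if (length(dup))
    stop("duplicate date(s): ", paste(unique(dup), collapse = ", "))
  ord <- order(date)
  date <- date[ord]
  abundance <- abundance[ord, , drop = FALSE]
  if (!is.null(depth)) {
    depth <- as.numeric(depth)[ord]
    if (length(depth) != length(date))
      stop("depth must have one value per section")
    if (any(diff(depth) >= 0))
      stop("depth must be strictly decreasing towards the most recent section")
  }
  rownames(abundance) <- NULL
  structure(list(date = date, abundance = abundance, depth = depth),
            class = "core_series")
}

parse_dates <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  d <- suppressWarnings(as.numeric(x))
  if (!anyNA(d)) return(d)
  iso <- as.Date(x, format = "%Y-%m-%d")
  if (anyNA(iso)) stop("dates must be numeric years or ISO dates (YYYY-MM-DD)")
  yr <- as.integer(format(iso, "%Y"))
  start <- as.Date(paste0(yr, "-01-01"))
  len <- as.numeric(as.Date(paste0(yr + 1L, "-01-01")) - start)
  yr + as.numeric(iso - start) / len
}

as_core_series <- function(x) {
  if (inherits(x, "core_series")) return(x)
  stop("expected a core_series object; see core_series() or read_core()")
}

#' @export
print.core_series <- function(x, ...) {
  cat("Community core: ", length(x$date), " sections (",
      format(min(x$date), digits = 6), " to ",
      format(max(x$date), digits = 6), "), ",
      ncol(x$abundance), " species",
      if (!is.null(x$depth)) ", with depths" else "", "\n", sep = "")
  invisible(x)
}

#' Read a community core from CSV
#'
#' Expects a header row; the first column is the section date, an optional
#' `depth_cm` column holds depths, and every remaining column is a species
#' percentage-abundance series.  Rows are sorted by date; duplicate dates,
#' negative abundances and unparseable dates are rejected.
#'
#' @param path Path to a CSV file.
#' @return A [core_series()] object.
#' @export
read_core <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("malformed header: need a date column plus at least one species")
  depth <- NULL
  cols <- names(tab)[-1L]
  if ("depth_cm" %in% cols) {
    depth <- as.numeric(tab[["depth_cm"]])
    tab <- tab[, names(tab) != "depth_cm", drop = FALSE]
  }
  ab <- as.matrix(tab[, -1L, drop = FALSE])
  core_series(date = tab[[1L]], abundance = ab, depth = depth)
}

#' Write a community core to CSV
#'
#' Inverse of [read_core()]: a read-write-read round trip reproduces the
#' core exactly (up to numeric formatting).
#'
#' @param core A [core_series()] object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_core <- function(core, path) {
  core <- as_core_series(core)
  tab <- data.frame(date = core$date, check.names = FALSE)
  if (!is.null(core$depth)) tab$depth_cm <- core$depth
  tab <- cbind(tab, as.data.frame(core$abundance, check.names = FALSE))
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles the tunable parameters of [run_pipeline()] with their defaults.
#' Unknown parameters are rejected.
#'
#' @param window Sections per incidence matrix and paired points per
#'   pretransition window (default 15).
#' @param min_lead_in Minimum number of lead-in difference pairs required
#'   before a lead-in coefficient is reported (default 5).
#' @param strong Margin by which the pretransition coefficient must fall
#'   below the lead-in coefficient for a keystone-favoured call
#'   (default 0.3).
#' @param alpha Two-sided significance level used both for the
#'   correlation diagnostic and for break-point detection (default 0.05).
#' @param cutoff Minimum regime length, in points, for break-point
#'   detection (default 5).
#' @param huber Huber weight parameter for regime means (default 1).
#' @param min_pct Presence threshold passed to [build_incidence()]
#'   (default 0).
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(window = 15L, min_lead_in = 5L, strong = 0.3,
                            alpha = 0.05, cutoff = 5L, huber = 1,
                            min_pct = 0) {
  cfg <- list(window = as.integer(window),
              min_lead_in = as.integer(min_lead_in),
              strong = strong, alpha = alpha, cutoff = as.integer(cutoff),
              huber = huber, min_pct = min_pct)
  stopifnot(cfg$window >= 3L, cfg$min_lead_in >= 2L, cfg$alpha > 0,
            cfg$alpha < 1, cfg$cutoff >= 2L, cfg$huber > 0)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full disorder-biodiversity diagnostic workflow
#'
#' Orchestrates the analysis stages on one core: sliding-window disorder
#' ([disorder_series()]), per-section biodiversity ([core_diversity()]),
#' pairing and first differences, sequential pretransition/lead-in
#' correlations with regime classification ([sequential_correlations()],
#' [classify_regime()]), and break-point detection ([stars_detect()]) on
#' both the disorder and biodiversity series.  Errors are re-signalled
#' with the name of the failing stage.
#'
#' @param core A [core_series()] object, or a path to a core CSV.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, the stage outputs are
#'   written as CSV files plus a JSON run manifest.
#' @return A list with elements `disorder`, `diversity`, `paired`,
#'   `diffs`, `signal` (one data frame per channel, with regime labels),
#'   `breaks` (STARS results for the disorder and N2 series) and
#'   `manifest` (resolved configuration, package version, input summary).
#' @export
run_pipeline <- function(core, config = pipeline_config(), out_dir = NULL) {
  if (is.character(core)) core <- stage("read_core", read_core(core))
  core <- as_core_series(core)
  if (!inherits(config, "pipeline_config"))
    stop("config must come from pipeline_config()")
  if (length(core$date) < 2L * config$window)
    stop("in stage 'disorder': core has ", length(core$date),
         " sections; the diagnostic needs at least ", 2L * config$window)

  dis <- stage("disorder", disorder_series(core, window = config$window,
                                           min_pct = config$min_pct))
  div <- stage("diversity", core_diversity(core))
  paired <- stage("pair", pair_series(dis, div))
  diffs <- stage("differences", first_differences(paired))
  sig <- lapply(c(n2 = "n2", richness = "richness"), function(ch)
    stage("signal", {
      sc <- sequential_correlations(diffs, window = config$window,
                                    min_lead_in = config$min_lead_in,
                                    channel = ch)
      sc$regime <- classify_regime(sc$pre_r, sc$pre_p, sc$lead_r,
                                   strong = config$strong,
                                   alpha = config$alpha)
      sc
    }))
  brk <- stage("breakpoints", list(
    disorder = stars_detect(paired$temperature, dates = paired$date,
                            alpha = config$alpha, cutoff = config$cutoff,
                            huber = config$huber),
    n2 = stars_detect(paired$n2, dates = paired$date,
                      alpha = config$alpha, cutoff = config$cutoff,
                      huber = config$huber)
  ))
  manifest <- list(
    package = "ecodisorder",
    version = as.character(utils::packageVersion("ecodisorder")),
    config = unclass(config),
    n_sections = length(core$date),
    n_species = ncol(core$abundance),
    date_range = range(core$date),
    final_pretransition = list(
      n2 = tail_row(sig$n2), richness = tail_row(sig$richness))
  )
  out <- list(disorder = dis, diversity = div, paired = paired,
              diffs = diffs, signal = sig, breaks = brk,
              manifest = manifest)
  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  out
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("in stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

tail_row <- function(df) {
  r <- df[nrow(df), c("date", "pre_r", "pre_p", "lead_r", "lead_p", "regime")]
  r$regime <- as.character(r$regime)
  as.list(r)
}

write_pipeline <- function(out, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) write.csv(df, file.path(out_dir, f), row.names = FALSE)
  wr(out$disorder, "disorder.csv")
  wr(out$diversity, "diversity.csv")
  wr(out$paired, "paired.csv")
  wr(out$diffs, "differences.csv")
  wr(out$signal$n2, "signal_n2.csv")
  wr(out$signal$richness, "signal_richness.csv")
  brk <- do.call(rbind, lapply(names(out$breaks), function(nm) {
    b <- out$breaks[[nm]]
    if (length(b$breaks) == 0L) return(NULL)
    data.frame(series = nm, index = b$breaks, date = b$break_dates,
               rsi = b$rsi)
  }))
  if (!is.null(brk)) wr(brk, "breakpoints.csv")
  jsonlite::write_json(out$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
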