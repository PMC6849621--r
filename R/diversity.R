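# Biodiversity measures on percentage-abundance vectors.

#' Hill's N2 diversity on square-root transformed percentage abundances
#'
#' Computes Hill's second-order diversity number, the effective number of
#' common species, as `1 / sum(p_i^2)`.  Proportional abundances `p_i` are
#' taken from the square roots of the percentage abundances, normalised to
#' sum to one, so the index weights common species less steeply than it
#' would on raw percentages.  This is the convention used throughout the
#' package when pairing biodiversity with compositional disorder.
#'
#' @param x Numeric vector of percentage abundances for one sample
#'   (values >= 0; they need not sum to 100).  Zeros are allowed and
#'   contribute nothing.
#' @return A single number in `[1, richness(x)]`.  `N2 = 1` for a
#'   single-species sample and `N2 = S` for `S` equally abundant species.
#' @examples
#' hill_n2(c(50, 25, 25))   # 2.914
#' hill_n2(c(10, 10, 10))   # 3: perfectly even
#' @seealso [richness()], [core_diversity()]
#' @export
hill_n2 <- function(x) {
  x <- check_abundances(x)
  pos <- x[x > 0]
  if (length(pos) == 0L)
    stop("diversity is undefined for an all-zero abundance vector")
  p <- sqrt(pos)
  p <- p / sum(p)
  1 / sum(p^2)
}

#' Species richness of an abundance vector
#'
#' @param x Numeric vector of percentage abundances (values >= 0).
#' @return Integer count of strictly positive entries.
#' @export
richness <- function(x) {
  x <- check_abundances(x)
  sum(x > 0)
}

#' Per-section biodiversity of a community time series
#'
#' Applies [hill_n2()] and [richness()] to every section of a core.
#'
#' @param core A [core_series()] object.
#' @return A data frame with columns `date`, `n2` and `richness`, one row
#'   per section.  Sections with no species present get `NA` for `n2` and
#'   0 for `richness`.
#' @export
core_diversity <- function(core) {
  core <- as_core_series(core)
  ab <- core$abundance
  n2 <- apply(ab, 1L, function(v) if (any(v > 0)) hill_n2(v) else NA_real_)
  data.frame(
    date = core$date,
    n2 = as.numeric(n2),
    richness = as.integer(apply(ab, 1L, richness)),
    row.names = NULL
  )
}

check_abundances <- function(x) {
  if (!is.numeric(x)) stop("abundances must be numeric")
  if (anyNA(x)) stop("abundances must not contain NA")
  if (any(x < 0)) stop("abundances must be non-negative")
  as.numeric(x)
}
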