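# Compositional disorder: nestedness temperature of binary incidence
# matrices built from sliding windows of community samples.
#
# Geometry. After canonical packing (rows by richness, columns by
# incidence), cell (i, j) of an m x n matrix sits at unit-square
# coordinates x = (i - 0.5)/m (down the rows, richest row at x ~ 0) and
# y = (j - 0.5)/n (along the columns, most incident species at y ~ 0).
# The fill line is the superellipse x^p + y^p = 1 with exponent p chosen
# so that the area on the presence side equals the matrix fill; presences
# are expected at y < (1 - x^p)^(1/p).  Each cell's deviation from the
# line is measured along the slope-one diagonal through the cell and
# normalised by the length of that diagonal inside the unit square.  The
# temperature is 100 * mean(squared normalised deviations of surprises) /
# 0.04145, where 0.04145 is the mean squared deviation attained by the
# theoretical maximally unexpected matrix; this calibration puts a fully
# disordered matrix at ~100 degrees and is the standard constant of the
# nestedness-temperature lineage.

#' Build a species incidence matrix from a window of core sections
#'
#' Takes the `window` consecutive sections ending at `end_index` and
#' records presence (abundance strictly above `min_pct`) of every species.
#' Species absent from all sections of the window are dropped: they carry
#' no information for that window.  Empty sections are retained as
#' all-zero rows: an empty sample is a real observation.
#'
#' @param core A [core_series()] object.
#' @param end_index Index of the most recent section of the window.
#' @param window Number of sections per window (default 15).
#' @param min_pct Minimum percentage abundance counting as presence
#'   (exclusive threshold; default 0, i.e. any positive abundance).
#' @return A binary matrix of class `"incidence_matrix"` with one row per
#'   section (oldest first, dates as row names), one column per retained
#'   species, and attributes `end_date` (date of the most recent section)
#'   and `fill` (proportion of presences).
#' @export
build_incidence <- function(core, end_index, window = 15L, min_pct = 0) {
  core <- as_core_series(core)
  n_sec <- length(core$date)
  end_index <- as.integer(end_index)
  if (end_index < window || end_index > n_sec)
    stop("need at least ", window, " sections at or before end_index")
  idx <- (end_index - window + 1L):end_index
  cells <- (core$abundance[idx, , drop = FALSE] > min_pct) * 1L
  rownames(cells) <- format(core$date[idx], trim = TRUE)
  keep <- colSums(cells) > 0L
  if (!any(keep)) stop("all sections in the window are empty")
  cells <- cells[, keep, drop = FALSE]
  structure(cells,
            end_date = core$date[end_index],
            fill = sum(cells) / length(cells),
            class = c("incidence_matrix", "matrix"))
}

#' Canonically pack an incidence matrix
#'
#' Sorts rows by richness (descending) and columns by incidence
#' (descending), so that presences concentrate towards the top left.
#' Ties are broken deterministically: first by the incidence-weighted sum
#' of the orthogonal marginals, then by the row/column 0/1 pattern
#' (presences first), and finally by label.  The packed form is therefore
#' identical for any row/column permutation of the same matrix.
#'
#' @param mat A binary matrix (0/1 or logical), e.g. from
#'   [build_incidence()].
#' @return An object of class `"packed_matrix"`: a list with elements
#'   `cells` (the packed binary matrix), `row_order` and `col_order` (the
#'   permutations applied), and `x`, `y` (unit-square coordinates of cell
#'   centres: `x` down the packed rows, `y` along the packed columns).
#' @export
pack_incidence <- function(mat) {
  cells <- as_binary_matrix(mat)
  m <- nrow(cells); n <- ncol(cells)
  ords <- canonical_orders(cells)
  packed <- cells[ords$row, ords$col, drop = FALSE]
  structure(list(
    cells = packed,
    row_order = ords$row,
    col_order = ords$col,
    x = (seq_len(m) - 0.5) / m,
    y = (seq_len(n) - 0.5) / n
  ), class = "packed_matrix")
}

# Canonical row/column orders: marginal totals, then incidence-weighted
# orthogonal marginals, then iterative refinement by presence counts
# within the other dimension's key classes (all content-based, hence
# permutation invariant).  Ties that survive refinement come in coupled
# row/column families (near-automorphisms); they are resolved by
# individualising each member of the first stalled class in turn and
# keeping the branch whose packed matrix is lexicographically smallest,
# which is again a function of content only.
canonical_orders <- function(cells, row_extra = list(), col_extra = list(),
                             depth = 0L) {
  m <- nrow(cells); n <- ncol(cells)
  rs <- rowSums(cells); cs <- colSums(cells)
  r2 <- as.vector(cells %*% cs)
  c2 <- as.vector(crossprod(cells, rs))
  if (length(row_extra) == 0L && length(col_extra) == 0L &&
      !anyDuplicated(complex(real = rs, imaginary = r2)) &&
      !anyDuplicated(complex(real = cs, imaginary = c2)))
    return(list(row = order(-rs, -r2), col = order(-cs, -c2)))
  rr <- key_ranks(c(list(-rs, -r2), row_extra))
  cr <- key_ranks(c(list(-cs, -c2), col_extra))
  for (it in 1:8) {
    if (!anyDuplicated(rr) && !anyDuplicated(cr)) break
    # rank compression: the current rank carries all earlier keys
    rr_new <- key_ranks(c(list(rr), neg_columns(cells %*% class_indicator(cr))))
    cr_new <- key_ranks(c(list(cr), neg_columns(crossprod(cells, class_indicator(rr)))))
    if (identical(rr_new, rr) && identical(cr_new, cr)) break  # stalled
    rr <- rr_new; cr <- cr_new
  }
  sep_class <- function(ranks, pats) {
    # first tied class holding at least two distinct patterns
    for (cls in sort(unique(ranks[duplicated(ranks)]))) {
      members <- which(ranks == cls)
      if (length(unique(pats[members])) > 1L)
        return(members)
    }
    integer(0)
  }
  done <- (!anyDuplicated(rr) && !anyDuplicated(cr)) || depth >= 6L
  mem_r <- if (done) integer(0) else
    sep_class(rr, apply(cells, 1L, paste, collapse = ""))
  mem_c <- if (done || length(mem_r)) integer(0) else
    sep_class(cr, apply(cells, 2L, paste, collapse = ""))
  if (done || (!length(mem_r) && !length(mem_c)))
    return(list(row = order(rr), col = order(cr)))
  # individualise each distinguishable member of the stalled class and
  # keep the branch whose packed pattern is lexicographically smallest
  branches <- if (length(mem_r)) {
    lapply(mem_r[seq_len(min(8L, length(mem_r)))], function(i)
      canonical_orders(cells, c(row_extra, list(-(seq_len(m) == i))),
                       col_extra, depth + 1L))
  } else {
    lapply(mem_c[seq_len(min(8L, length(mem_c)))], function(j)
      canonical_orders(cells, row_extra,
                       c(col_extra, list(-(seq_len(n) == j))), depth + 1L))
  }
  pats <- vapply(branches, function(b)
    paste(cells[b$row, b$col], collapse = ""), character(1))
  branches[[order(pats)[1L]]]
}

# Dense rank of each item under the lexicographic tuple of keys.
key_ranks <- function(keys) {
  ord <- do.call(order, keys)
  len <- length(ord)
  if (len < 2L) return(rep(1L, len))
  neq <- logical(len - 1L)
  for (k in keys) neq <- neq | k[ord[-1L]] != k[ord[-len]]
  r <- integer(len)
  r[ord] <- cumsum(c(1L, neq))
  r
}

# Indicator matrix (items x classes) of the key classes, classes in key
# order.
class_indicator <- function(ranks) {
  outer(ranks, sort(unique(ranks)), "==") * 1
}

neg_columns <- function(mat) {
  lapply(seq_len(ncol(mat)), function(j) -mat[, j])
}

#' @export
print.packed_matrix <- function(x, ...) {
  cat("Packed incidence matrix: ", nrow(x$cells), " samples x ",
      ncol(x$cells), " species, fill ",
      format(mean(x$cells), digits = 3), "\n", sep = "")
  invisible(x)
}

#' Area under the fill line for a given exponent
#'
#' The fill line in the unit square is `y = (1 - (1 - x)^p)^(1/p)`; its
#' enclosed area is a strictly increasing function of `p`, ranging from 0
#' (p -> 0) to 1 (p -> Inf), with area 1/2 at `p = 1` (the diagonal).
#'
#' @param p Fill-line exponent (> 0).
#' @return The area under the curve over `[0, 1]`.
#' @export
fill_line_area <- function(p) {
  stopifnot(is.numeric(p), p > 0)
  vapply(p, function(pp)
    integrate(function(x) (1 - (1 - x)^pp)^(1 / pp), 0, 1,
              rel.tol = 1e-11)$value,
    numeric(1))
}

#' Solve the fill-line exponent for a given matrix fill
#'
#' Finds `p` such that the fill line `y = (1 - (1 - x)^p)^(1/p)` encloses
#' an area equal to `fill`, by monotone bracketing and root refinement on
#' `log(p)` (the area is strictly increasing in `p`).
#'
#' @param fill Proportion of presences, strictly between 0 and 1.
#' @return The exponent `p` (> 0).  `fill = 0.5` gives `p = 1` (the line
#'   `y = x`).
#' @export
fill_line_exponent <- function(fill) {
  stopifnot(is.numeric(fill), length(fill) == 1L)
  if (!(fill > 0 && fill < 1))
    stop("fill must be strictly between 0 and 1 (an empty matrix has no ",
         "fill line; a full matrix has temperature 0 by definition)")
  cached <- fill_exp_cache_get(fill)
  if (!is.null(cached)) return(cached)
  p <- exp(uniroot(function(lp) fill_line_area(exp(lp)) - fill,
                   interval = c(-12, 12), tol = 1e-13)$root)
  fill_exp_cache_set(fill, p)
  p
}

# Exponent cache: fills are rationals k/(m*n), so sliding windows and
# simulations revisit the same values constantly.
.fill_exp_cache <- new.env(parent = emptyenv())
.fill_exp_cache$n <- 0L
fill_exp_cache_get <- function(fill) {
  get0(sprintf("c%.15g", fill), envir = .fill_exp_cache, inherits = FALSE)
}
fill_exp_cache_set <- function(fill, p) {
  if (.fill_exp_cache$n > 8192L) {
    rm(list = ls(.fill_exp_cache), envir = .fill_exp_cache)
    .fill_exp_cache$n <- 0L
  }
  .fill_exp_cache$n <- .fill_exp_cache$n + 1L
  assign(sprintf("c%.15g", fill), p, envir = .fill_exp_cache)
}

#' Surprise cells of a packed matrix
#'
#' A surprise is a presence on the absence side of the fill line, or an
#' absence on the presence side, provided the cell also witnesses an
#' actual violation of nestedness in the packed matrix: a surprising
#' presence must have an absence above it in its column or to its left in
#' its row, and a surprising absence must have a presence below it in its
#' column or to its right in its row.  This condition makes every
#' subset-chain (perfectly nested) matrix surprise-free regardless of how
#' its richness profile compares with the smooth fill-line family, so a
#' perfectly nested community scores exactly 0 degrees.
#'
#' Each surprise carries the squared deviation of the cell centre from the
#' fill line, measured along the slope-one diagonal through the cell and
#' normalised by the length of that diagonal inside the unit square.
#'
#' @param packed A `"packed_matrix"` from [pack_incidence()].
#' @param p Fill-line exponent from [fill_line_exponent()] for the same
#'   matrix.
#' @return A data frame with one row per surprise: `row`, `col` (packed
#'   positions), `presence` (logical), `deviation` (normalised, > 0) and
#'   `sq_deviation`.  The full m x n matrix of squared deviations (zero at
#'   non-surprise cells) is attached as attribute `"u2"`.
#' @export
surprises <- function(packed, p) {
  if (!inherits(packed, "packed_matrix"))
    stop("`packed` must come from pack_incidence()")
  cells <- packed$cells
  m <- nrow(cells); n <- ncol(cells)
  xr <- (seq_len(m) - 0.5) / m          # row coordinate, down
  yc <- (seq_len(n) - 0.5) / n          # column coordinate, right
  line_at_row <- (1 - xr^p)^(1 / p)     # fill line height per row
  pres <- cells == 1L
  # which side of the fill line: presence expected at y < line(x)
  absence_side <- outer(xr, yc, function(x, y) y) >
    matrix(line_at_row, m, n)
  wrong_side <- (pres & absence_side) | (!pres & !absence_side)
  cand <- wrong_side & nestedness_violations(pres)
  idx <- which(cand, arr.ind = TRUE)
  u2 <- matrix(0, m, n)
  out <- data.frame(row = integer(0), col = integer(0),
                    presence = logical(0), deviation = numeric(0),
                    sq_deviation = numeric(0))
  if (nrow(idx)) {
    x0 <- xr[idx[, 1L]]
    a <- yc[idx[, 2L]] - x0
    dev <- abs(x0 - crossing_points(a, p)) / (1 - abs(a))
    u2[idx] <- dev^2
    ord <- order(idx[, 1L], idx[, 2L])
    out <- data.frame(row = as.integer(idx[ord, 1L]),
                      col = as.integer(idx[ord, 2L]),
                      presence = pres[idx][ord],
                      deviation = dev[ord],
                      sq_deviation = dev[ord]^2)
  }
  rownames(out) <- NULL
  attr(out, "u2") <- u2
  out
}

# Crossing of the fill line y = (1 - x^p)^(1/p) with the slope-one
# diagonal y = x + a, by vectorised bisection (the line is strictly
# decreasing, so the root is unique).
crossing_points <- function(a, p) {
  lo <- numeric(length(a)); hi <- lo + 1
  for (it in 1:40) {
    mid <- (lo + hi) / 2
    above <- (1 - mid^p)^(1 / p) - mid - a > 0
    lo[above] <- mid[above]
    hi[!above] <- mid[!above]
  }
  (lo + hi) / 2
}

# Which cells break nestedness in a packed matrix: presences with a
# missing species in a richer (higher) row of the same column or an
# absent more-incident species to the left of the same row; dually for
# absences.
nestedness_violations <- function(pres) {
  m <- nrow(pres); n <- ncol(pres)
  absn <- !pres
  abs_above <- apply(absn, 2L, cumsum) - absn > 0
  abs_left <- t(apply(absn, 1L, cumsum)) - absn > 0
  pres_below <- apply(pres[m:1, , drop = FALSE], 2L, cumsum)[m:1, , drop = FALSE] - pres > 0
  pres_right <- t(apply(pres[, n:1, drop = FALSE], 1L, cumsum))[, n:1, drop = FALSE] - pres > 0
  (pres & (abs_above | abs_left)) | (absn & (pres_below | pres_right))
}

#' Nestedness temperature (degrees of compositional disorder)
#'
#' Runs the full pipeline pack -> fill line -> surprises -> scale and
#' returns the temperature of an incidence matrix on the 0-100 degree
#' scale: 0 for a completely nested (subset-chain) community, rising with
#' compositional disorder towards 100 for a maximally unexpected matrix.
#'
#' @param mat A binary incidence matrix (samples x species), e.g. from
#'   [build_incidence()] or [generate_matrix()].  Columns with no
#'   presences are dropped before computing the fill.
#' @return An object of class `"disorder_value"`: a list with
#'   `temperature` (degrees in `[0, 100]`), `n_surprises`, `sum_sq`
#'   (sum of squared normalised deviations), `fill`, `p` (fill-line
#'   exponent, `NA` for a full matrix), and matrix dimensions `m`, `n`.
#' @examples
#' m <- generate_matrix("nested", 15, 20, fill = 0.4, seed = 1)
#' disorder_temperature(m)$temperature  # 0
#' @export
disorder_temperature <- function(mat) {
  cells <- as_binary_matrix(mat)
  cells <- cells[, colSums(cells) > 0, drop = FALSE]
  if (ncol(cells) == 0L) stop("matrix has no presences")
  m <- nrow(cells); n <- ncol(cells)
  fill <- sum(cells) / (m * n)
  if (fill >= 1) {
    out <- list(temperature = 0, n_surprises = 0L, sum_sq = 0,
                fill = 1, p = NA_real_, m = m, n = n)
    class(out) <- "disorder_value"
    return(out)
  }
  packed <- pack_incidence(cells)
  p <- fill_line_exponent(fill)
  st <- surprise_stats(packed$cells, p)
  # 0.04145: mean squared normalised deviation of the theoretical
  # maximally unexpected matrix; scales that worst case to 100 degrees.
  temp <- min(100, 100 * st$ss / (m * n) / 0.04145)
  out <- list(temperature = temp, n_surprises = st$n, sum_sq = st$ss,
              fill = fill, p = p, m = m, n = n)
  class(out) <- "disorder_value"
  out
}

# Sum of squared surprise deviations without the per-cell bookkeeping
# of surprises(); same classification and geometry.
surprise_stats <- function(cells, p) {
  m <- nrow(cells); n <- ncol(cells)
  xr <- (seq_len(m) - 0.5) / m
  yc <- (seq_len(n) - 0.5) / n
  line_at_row <- (1 - xr^p)^(1 / p)
  pres <- cells == 1L
  absence_side <- matrix(yc, m, n, byrow = TRUE) > line_at_row
  wrong_side <- (pres & absence_side) | (!pres & !absence_side)
  idx <- which(wrong_side & nestedness_violations(pres), arr.ind = TRUE)
  if (!nrow(idx)) return(list(ss = 0, n = 0L))
  x0 <- xr[idx[, 1L]]
  a <- yc[idx[, 2L]] - x0
  dev <- (x0 - crossing_points(a, p)) / (1 - abs(a))
  list(ss = sum(dev^2), n = nrow(idx))
}

#' @export
print.disorder_value <- function(x, ...) {
  cat(sprintf("disorder: %.2f deg (%d surprises, %d x %d matrix, fill %.3f)\n",
              x$temperature, x$n_surprises, x$m, x$n, x$fill))
  invisible(x)
}

#' Sliding-window disorder series of a community time series
#'
#' Computes the nestedness temperature for every window of `window`
#' consecutive sections, dated by the window's most recent section, from
#' the `window`-th section to the end of the core.  Each value is intended
#' to be paired downstream with the biodiversity of that same most recent
#' section (see [pair_series()]).
#'
#' @inheritParams build_incidence
#' @param window Sections per incidence matrix (default 15).
#' @return Data frame with one row per eligible section: `date`,
#'   `temperature`, `n_species` (species retained in the window), `fill`.
#' @export
disorder_series <- function(core, window = 15L, min_pct = 0) {
  core <- as_core_series(core)
  n_sec <- length(core$date)
  if (n_sec < window)
    stop("core has ", n_sec, " sections; at least ", window, " are needed")
  ends <- seq.int(window, n_sec)
  vals <- vapply(ends, function(e) {
    inc <- build_incidence(core, e, window = window, min_pct = min_pct)
    dv <- disorder_temperature(inc)
    c(dv$temperature, dv$n, dv$fill)
  }, numeric(3))
  data.frame(date = core$date[ends], temperature = vals[1L, ],
             n_species = as.integer(vals[2L, ]), fill = vals[3L, ])
}

as_binary_matrix <- function(mat) {
  if (inherits(mat, "packed_matrix")) mat <- mat$cells
  if (!is.matrix(mat)) stop("expected a matrix of 0/1 values")
  if (is.logical(mat)) mat <- mat * 1L
  if (anyNA(mat) || any(mat != 0 & mat != 1))
    stop("incidence matrix cells must be 0 or 1")
  if (nrow(mat) < 1L || ncol(mat) < 1L) stop("matrix must be non-empty")
  mat
}
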