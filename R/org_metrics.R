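#' Best-r: strongest axis-wise order correlation
#'
#' For an ordered sequence of collected targets, computes the Pearson
#' correlation between collection order (1, 2, 3, ...) and the x coordinates,
#' and between order and the y coordinates, and returns the larger of the two
#' in absolute value.  Reading- or scanner-like searches (strong horizontal
#' or vertical sweeps) give values near 1; disorganized searches give values
#' near 0.  Spiral searches are a known blind spot: they are organized but
#' have no monotone axis component.
#'
#' A coordinate axis with zero variance has no defined correlation and simply
#' contributes nothing (the other axis alone supplies the value); if both
#' axes are constant the indicator is undefined.
#'
#' @param x,y pick-time coordinates in collection order (pixels).
#' @return A number in `[0, 1]`, or `NA` with a `"reason"` attribute
#'   (`"too_few_picks"`, `"zero_variance"`) when undefined.
#' @examples
#' best_r(1:10, runif(10))          # 1: strictly increasing x
#' best_r(c(0, 2, 1, 3), rep(0, 4)) # 0.8
#' @export
best_r <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3L) return(structure(NA_real_, reason = "too_few_picks"))
  ord <- seq_len(n)
  vx <- stats::var(x) > 0
  vy <- stats::var(y) > 0
  if (!vx && !vy) return(structure(NA_real_, reason = "zero_variance"))
  rs <- c(if (vx) abs(stats::cor(ord, x)),
          if (vy) abs(stats::cor(ord, y)))
  max(rs)
}

#' Mean intertarget distance (ITD)
#'
#' Arithmetic mean of the Euclidean distances between consecutively collected
#' targets, in pixels.  Shorter mean ITD indicates a more organized search,
#' though it also shrinks mechanically with item density.
#'
#' @inheritParams best_r
#' @return Mean consecutive distance (pixels), or `NA` with a `"reason"`
#'   attribute for fewer than 2 picks.
#' @examples
#' mean_itd(c(0, 3, 3), c(0, 4, 8))  # (5 + 4) / 2 = 4.5
#' @export
mean_itd <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 2L) return(structure(NA_real_, reason = "too_few_picks"))
  mean(sqrt(diff(x)^2 + diff(y)^2))
}

#' Percentage above the optimal scan-path (PAO)
#'
#' Compares the realized scan-path length against the shortest open
#' Hamiltonian path through the same pick-time coordinates:
#' `PAO = (actual / optimal - 1) * 100`.  A PAO of 0 means the observer's
#' order was itself optimal; 50 means the realized path was 1.5 times the
#' optimal length; 100 means double.
#'
#' When the optimum comes from the heuristic solver it can, in rare cases,
#' exceed the realized length (the realized order is itself a Hamiltonian
#' path and thus an upper bound on the true optimum).  In that case the
#' realized length replaces the heuristic value, so PAO is never negative.
#'
#' @inheritParams best_r
#' @param mode,exact_max passed to [optimal_open_path()].
#' @return PAO in percent (`>= 0`), or `NA` with a `"reason"` attribute
#'   (`"too_few_picks"`, `"degenerate_geometry"` when all picks coincide).
#' @examples
#' # picks along a line, visited out of order: actual 4/3 of the span
#' pao(c(1, 0, 3), c(0, 0, 0))  # 33.33
#' @export
pao <- function(x, y, mode = "auto", exact_max = 10L) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3L) return(structure(NA_real_, reason = "too_few_picks"))
  actual <- sum(sqrt(diff(x)^2 + diff(y)^2))
  opt <- optimal_open_path(x, y, mode = mode, exact_max = exact_max)$length
  if (opt <= 0) return(structure(NA_real_, reason = "degenerate_geometry"))
  if (opt > actual) opt <- actual  # realized path bounds the true optimum
  (actual / opt - 1) * 100
}

#' Score one pick sequence on all four organization indicators
#'
#' Bundles [best_r()], [mean_itd()], [pao()] and [intersection_rate()] for a
#' single ordered pick sequence (a whole trial or one time bin).  Each
#' indicator is computed when its minimum pick count is met and reported as
#' `NA` with a reason code otherwise — never silently zero.
#'
#' @inheritParams best_r
#' @param bin_label label recorded with the scores (`"whole"`, `"bin1"`,
#'   `"bin2"`).
#' @param exact_max exact-solver threshold for [pao()].
#' @return One-row `data.frame`: `bin`, `n_picks`, `best_r`, `mean_itd`,
#'   `pao`, `intersection_rate`, and a semicolon-separated `reasons` column
#'   naming any undefined indicators.
#' @export
score_sequence <- function(x, y, bin_label = "whole", exact_max = 10L) {
  vals <- list(
    best_r = best_r(x, y),
    mean_itd = mean_itd(x, y),
    pao = pao(x, y, exact_max = exact_max),
    intersection_rate = intersection_rate(x, y))
  reasons <- vapply(names(vals), function(nm) {
    r <- attr(vals[[nm]], "reason")
    if (is.null(r)) "" else paste0(nm, ":", r)
  }, character(1))
  reasons <- paste(reasons[nzchar(reasons)], collapse = ";")
  data.frame(bin = bin_label, n_picks = length(x),
             best_r = as.numeric(vals$best_r),
             mean_itd = as.numeric(vals$mean_itd),
             pao = as.numeric(vals$pao),
             intersection_rate = as.numeric(vals$intersection_rate),
             reasons = reasons, stringsAsFactors = FALSE)
}
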