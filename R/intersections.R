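#' Count self-crossings of a scan-path
#'
#' Counts unordered pairs of non-adjacent scan-path segments that intersect.
#' The polyline is the sequence of straight segments between consecutively
#' collected targets; segments sharing an endpoint (adjacent picks) are never
#' counted.  Crossings indicate back-tracking over already-searched regions,
#' i.e. a less organized search.
#'
#' Degenerate geometry is resolved deterministically: a non-adjacent segment
#' passing exactly through another segment's endpoint counts as one
#' intersection, and two overlapping collinear non-adjacent segments also
#' count as one.  Orientation tests use an epsilon of `1e-9` times the
#' bounding-box scale of the points.
#'
#' @param x,y pick-time coordinates in collection order.
#' @return Integer count of crossing pairs; `0` for fewer than 4 picks
#'   (no pair of non-adjacent segments exists).
#' @examples
#' count_intersections(c(0, 1, 1, 0), c(0, 1, 0, 1))  # the "bowtie": 1
#' @export
count_intersections <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 4L) return(0L)
  scale <- max(diff(range(x)), diff(range(y)), 1e-300)
  eps <- 1e-9 * scale
  count <- 0L
  nseg <- n - 1L
  for (i in seq_len(nseg - 2L)) {
    for (j in (i + 2L):nseg) {
      if (segments_cross(x[i], y[i], x[i + 1L], y[i + 1L],
                         x[j], y[j], x[j + 1L], y[j + 1L], eps))
        count <- count + 1L
    }
  }
  count
}

#' Scan-path intersection rate
#'
#' Number of scan-path self-crossings divided by the number of targets
#' collected, which makes trials with different numbers of picks comparable.
#'
#' @inheritParams count_intersections
#' @return Crossings per collected target; `NA` with a `"reason"` attribute
#'   for fewer than 4 picks.
#' @export
intersection_rate <- function(x, y) {
  n <- length(x)
  if (n < 4L)
    return(structure(NA_real_, reason = "too_few_picks"))
  count_intersections(x, y) / n
}

# Orientation/straddle segment test.  Signed area cross-products with an
# absolute epsilon; collinear overlaps and endpoint touches count as hits.
segments_cross <- function(ax, ay, bx, by, cx, cy, dx, dy, eps) {
  d1 <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  d2 <- (bx - ax) * (dy - ay) - (by - ay) * (dx - ax)
  d3 <- (dx - cx) * (ay - cy) - (dy - cy) * (ax - cx)
  d4 <- (dx - cx) * (by - cy) - (dy - cy) * (bx - cx)
  if (((d1 > eps && d2 < -eps) || (d1 < -eps && d2 > eps)) &&
      ((d3 > eps && d4 < -eps) || (d3 < -eps && d4 > eps)))
    return(TRUE)
  # degenerate: some endpoint collinear with the other segment
  if (abs(d1) <= eps && on_segment(ax, ay, bx, by, cx, cy, eps)) return(TRUE)
  if (abs(d2) <= eps && on_segment(ax, ay, bx, by, dx, dy, eps)) return(TRUE)
  if (abs(d3) <= eps && on_segment(cx, cy, dx, dy, ax, ay, eps)) return(TRUE)
  if (abs(d4) <= eps && on_segment(cx, cy, dx, dy, bx, by, eps)) return(TRUE)
  FALSE
}

# Is point p on segment ab, assuming p is (near-)collinear with ab?
on_segment <- function(ax, ay, bx, by, px, py, eps) {
  px >= min(ax, bx) - eps && px <= max(ax, bx) + eps &&
    py >= min(ay, by) - eps && py <= max(ay, by) + eps
}
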