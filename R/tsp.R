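#' Shortest open Hamiltonian path through a point set
#'
#' Finds (exactly or heuristically) the shortest open path that visits every
#' point once, with both endpoints free.  This is the optimal scan-path used
#' as the denominator of the percentage-above-optimal (PAO) indicator: an
#' observer's realized pick order is one Hamiltonian path among many, and the
#' shortest one is the yardstick it is compared against.
#'
#' For `n` up to `exact_max` points the solver is a Held-Karp style dynamic
#' program over subsets with free endpoints, which is globally optimal.
#' Beyond that it runs nearest-neighbour constructions from every start point
#' and refines the best with 2-opt moves until no improving reversal exists.
#'
#' @param x,y numeric coordinate vectors (pixels), one point each.
#' @param mode `"auto"` (exact up to `exact_max`, else heuristic), `"exact"`,
#'   or `"heuristic"`.
#' @param exact_max largest `n` handled by the exact dynamic program in
#'   `"auto"` mode (default 10; `2^n * n^2` states).
#' @return A list of class `"path_solution"` with elements `order`
#'   (permutation of point indices), `length` (pixels), and `method`
#'   (`"exact_dp"`, `"heuristic_2opt"`, or `"degenerate"`).
#' @examples
#' sol <- optimal_open_path(c(0, 5, 2, 9), c(0, 0, 0, 0))
#' sol$length  # 9: the span of collinear points
#' @export
optimal_open_path <- function(x, y, mode = c("auto", "exact", "heuristic"),
                              exact_max = 10L) {
  mode <- match.arg(mode)
  n <- length(x)
  stopifnot(length(y) == n)
  if (n == 0L) stop("optimal_open_path: empty point set")
  if (n == 1L) {
    return(structure(list(order = 1L, length = 0, method = "degenerate"),
                     class = "path_solution"))
  }
  D <- as.matrix(stats::dist(cbind(x, y)))
  if (n == 2L) {
    return(structure(list(order = 1:2, length = D[1, 2], method = "degenerate"),
                     class = "path_solution"))
  }
  exact <- switch(mode,
    exact = TRUE,
    heuristic = FALSE,
    auto = n <= exact_max)
  if (exact && n > 20L)
    stop("exact open-path solver limited to n <= 20 (requested n = ", n, ")")
  sol <- if (exact) path_exact_dp(D) else path_heuristic(D)
  structure(sol, class = "path_solution")
}

#' @export
#' @method print path_solution
print.path_solution <- function(x, ...) {
  cat(sprintf("Open Hamiltonian path: n = %d, length = %.3f (%s)\n",
              length(x$order), x$length, x$method))
  invisible(x)
}

# Held-Karp over subsets, free endpoints: dp[mask, j] = shortest path that
# visits exactly the points in mask and ends at j.
path_exact_dp <- function(D) {
  n <- nrow(D)
  nmask <- bitwShiftL(1L, n)
  dp <- matrix(Inf, nrow = nmask, ncol = n)
  par <- matrix(0L, nrow = nmask, ncol = n)
  for (j in seq_len(n)) dp[bitwShiftL(1L, j - 1L) + 1L, j] <- 0
  for (mask in seq_len(nmask - 1L)) {
    row <- dp[mask + 1L, ]
    live <- which(is.finite(row))
    if (!length(live)) next
    for (j in live) {
      base <- row[j]
      for (k in seq_len(n)) {
        bit <- bitwShiftL(1L, k - 1L)
        if (bitwAnd(mask, bit) != 0L) next
        nm <- mask + bit
        cand <- base + D[j, k]
        if (cand < dp[nm + 1L, k]) {
          dp[nm + 1L, k] <- cand
          par[nm + 1L, k] <- j
        }
      }
    }
  }
  full <- nmask - 1L
  end <- which.min(dp[full + 1L, ])
  best <- dp[full + 1L, end]
  # backtrack
  ord <- integer(n)
  mask <- full
  j <- end
  for (i in n:1) {
    ord[i] <- j
    pj <- par[mask + 1L, j]
    mask <- mask - bitwShiftL(1L, j - 1L)
    j <- pj
  }
  list(order = ord, length = best, method = "exact_dp")
}

path_len <- function(D, ord) {
  n <- length(ord)
  sum(D[cbind(ord[-n], ord[-1L])])
}

# Best nearest-neighbour construction over all starts, then 2-opt to a local
# optimum.  For an open path, reversing ord[i..j] replaces at most the two
# boundary edges (one if the reversal touches an endpoint).
path_heuristic <- function(D) {
  n <- nrow(D)
  best_ord <- NULL
  best_len <- Inf
  for (s in seq_len(n)) {
    ord <- integer(n)
    used <- rep(FALSE, n)
    ord[1L] <- s
    used[s] <- TRUE
    for (i in 2:n) {
      d <- D[ord[i - 1L], ]
      d[used] <- Inf
      k <- which.min(d)
      ord[i] <- k
      used[k] <- TRUE
    }
    len <- path_len(D, ord)
    if (len < best_len) {
      best_len <- len
      best_ord <- ord
    }
  }
  res <- two_opt(D, best_ord, best_len)
  list(order = res$ord, length = res$len, method = "heuristic_2opt")
}

two_opt <- function(D, ord, len, max_pass = 50L) {
  n <- length(ord)
  eps <- 1e-12 * max(D)
  for (pass in seq_len(max_pass)) {
    improved <- FALSE
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (i == 1L && j == n) next  # full reversal changes nothing
        delta <- 0
        if (i > 1L) delta <- delta + D[ord[i - 1L], ord[j]] - D[ord[i - 1L], ord[i]]
        if (j < n)  delta <- delta + D[ord[i], ord[j + 1L]] - D[ord[j], ord[j + 1L]]
        if (delta < -eps) {
          ord[i:j] <- ord[j:i]
          len <- len + delta
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  list(ord = ord, len = path_len(D, ord))
}
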