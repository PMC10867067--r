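# Independent oracles used to cross-check the package's geometry code.
# These deliberately use different algorithms from the implementation:
# exhaustive permutation enumeration for the shortest open path, and a
# parametric line-line solver for segment crossings.

# all permutations of 1..n as a matrix (rows), iterative construction
all_perms <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    p <- matrix(1L, 1, 1)
    if (n > 1) for (k in 2:n) {
      m <- nrow(p)
      out <- matrix(0L, m * k, k)
      for (pos in seq_len(k)) {
        rows <- (pos - 1L) * m + seq_len(m)
        out[rows, pos] <- k
        out[rows, -pos] <- p
      }
      p <- out
    }
    cache[[key]] <<- p
    p
  }
})

# global minimum open-path length by enumerating every visiting order
brute_open_path <- function(x, y) {
  n <- length(x)
  D <- as.matrix(dist(cbind(x, y)))
  P <- all_perms(n)
  lens <- rowSums(matrix(D[cbind(as.vector(P[, -n]), as.vector(P[, -1]))],
                         nrow = nrow(P)))
  min(lens)
}

# crossing test by solving p + t*(q-p) = r + u*(s-r) for (t, u); parallel,
# collinear, and zero-length segments are resolved by explicit point/interval
# logic under the same touch-counts-as-one convention the package documents
oracle_point_on <- function(a, b, pt, tol) {
  d <- b - a
  if (max(abs(d)) <= tol) return(max(abs(pt - a)) <= tol)
  cr <- d[1] * (pt - a)[2] - d[2] * (pt - a)[1]
  if (abs(cr) > tol * max(abs(d)) * max(abs(c(pt - a, 1)))) return(FALSE)
  tt <- sum((pt - a) * d) / sum(d * d)
  tt >= -tol && tt <= 1 + tol
}

oracle_segments_cross <- function(p, q, r, s, tol = 1e-9) {
  d1 <- q - p
  d2 <- s - r
  deg1 <- max(abs(d1)) <= tol
  deg2 <- max(abs(d2)) <= tol
  if (deg1 && deg2) return(max(abs(p - r)) <= tol)
  if (deg1) return(oracle_point_on(r, s, p, tol))
  if (deg2) return(oracle_point_on(p, q, r, tol))
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  scale <- max(abs(c(p, q, r, s)), 1)
  if (abs(den) > tol * scale^2) {
    rhs <- r - p
    t <- (rhs[1] * d2[2] - rhs[2] * d2[1]) / den
    u <- (rhs[1] * d1[2] - rhs[2] * d1[1]) / den
    return(t >= -tol && t <= 1 + tol && u >= -tol && u <= 1 + tol)
  }
  # parallel: cross only if collinear and the segments' extents overlap
  cr <- d1[1] * (r - p)[2] - d1[2] * (r - p)[1]
  if (abs(cr) > tol * scale^2) return(FALSE)
  oracle_point_on(p, q, r, tol) || oracle_point_on(p, q, s, tol) ||
    oracle_point_on(r, s, p, tol) || oracle_point_on(r, s, q, tol)
}

oracle_count_intersections <- function(x, y) {
  n <- length(x)
  if (n < 4) return(0L)
  cnt <- 0L
  for (i in 1:(n - 3)) {
    for (j in (i + 2):(n - 1)) {
      if (oracle_segments_cross(c(x[i], y[i]), c(x[i + 1], y[i + 1]),
                                c(x[j], y[j]), c(x[j + 1], y[j + 1])))
        cnt <- cnt + 1L
    }
  }
  cnt
}

# small well-formed trial log for data_io tests
make_trial_log <- function() {
  data.frame(
    participant = rep(c("p1", "p1", "p2"), times = c(3, 4, 3)),
    age = rep(c(8.2, 8.2, 14.5), times = c(3, 4, 3)),
    condition = rep(c("feature", "conjunction", "feature"),
                    times = c(3, 4, 3)),
    set_size = rep(c(60, 100, 140), times = c(3, 4, 3)),
    trial = rep(c(1, 2, 1), times = c(3, 4, 3)),
    order = c(1:3, 1:4, 1:3),
    x = c(10, 200, 350, 40, 80, 700, 900, 15, 400, 1200),
    y = c(500, 510, 490, 100, 900, 300, 820, 60, 61, 62),
    t = seq(0.5, 5, length.out = 10),
    item_class = rep(c("green", "green-square", "blue"), times = c(3, 4, 3)),
    is_target = TRUE,
    stringsAsFactors = FALSE)
}
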