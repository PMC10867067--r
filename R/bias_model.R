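#' Choice-model bias parameters
#'
#' Parameters of the sampling-without-replacement target-choice model.  At
#' every step the forager picks one of the remaining targets with
#' probability proportional to a product of four weights:
#'
#' * class preference `p_a`: weight `p_a` for targets of the reference class
#'   A, `1 - p_a` otherwise (the two-parameter "bag" model's preference);
#' * class stickiness `p_s`: weight `p_s` for targets of the same class as
#'   the previous pick, `1 - p_s` otherwise (runs vs. switches);
#' * proximity `rho_d >= 0`: weight `exp(-rho_d * d / s)` with `d` the
#'   distance from the previous pick and `s` a fixed distance scale
#'   (default: the display diagonal);
#' * direction persistence `rho_theta`: weight
#'   `exp(|rho_theta| * cos(dtheta - mu))` with `dtheta` the signed angle
#'   between the heading to the candidate and the previous movement
#'   direction.  The magnitude is the persistence strength; the sign only
#'   selects the preferred offset `mu` (0 when `rho_theta >= 0`, a lateral
#'   offset, default `-pi/2`, when negative), so only `|rho_theta|` is
#'   interpreted as strength.
#'
#' On the first pick of a trial only the class weight applies; on the second
#' pick there is no previous heading, so the direction weight is off.  With
#' `p_a = p_s = 0.5` and `rho_d = rho_theta = 0` every remaining target is
#' equally likely; with the spatial terms at 0 the model reduces exactly to
#' the two-parameter bag model.
#'
#' @param p_a,p_s probabilities in `[0, 1]`.
#' @param rho_d nonnegative proximity-bias strength.
#' @param rho_theta direction-persistence parameter (sign = side of the
#'   bias, magnitude = strength).
#' @return A classed list `"bias_params"`.
#' @export
bias_params <- function(p_a = 0.5, p_s = 0.5, rho_d = 0, rho_theta = 0) {
  stopifnot(p_a >= 0, p_a <= 1, p_s >= 0, p_s <= 1, rho_d >= 0)
  structure(list(p_a = p_a, p_s = p_s, rho_d = rho_d,
                 rho_theta = rho_theta,
                 abs_rho_theta = abs(rho_theta)),
            class = "bias_params")
}

#' @export
#' @method print bias_params
print.bias_params <- function(x, ...) {
  cat(sprintf(
    "Choice-model biases: p_a = %.3f, p_s = %.3f, rho_d = %.3f, rho_theta = %+.3f (|rho_theta| = %.3f)\n",
    x$p_a, x$p_s, x$rho_d, x$rho_theta, x$abs_rho_theta))
  invisible(x)
}

wrap_angle <- function(a) atan2(sin(a), cos(a))

#' Selection probabilities over the remaining targets
#'
#' Evaluates the choice model's probability of picking each remaining
#' target, given the previous pick (if any) and the previous movement
#' direction (if any).  See [bias_params()] for the weight definitions.
#'
#' @param remaining data.frame of remaining targets with columns `x`, `y`,
#'   `item_class`.
#' @param params a [bias_params()] object.
#' @param prev_xy length-2 numeric, coordinates of the previous pick, or
#'   `NULL` on the first pick.
#' @param prev_class class label of the previous pick, or `NULL`.
#' @param prev_angle previous movement direction (radians), or `NULL` when
#'   no heading exists yet.
#' @param ref_class label of class "A" for the preference weight; default:
#'   lexicographically first class among `remaining` and `prev_class`.
#' @param s distance standardization scale in pixels (default: diagonal of
#'   the standard 1400 x 1050 display).
#' @param mu_offset preferred angular offset used when `rho_theta < 0`.
#' @return Numeric probability vector summing to 1.
#' @export
selection_weights <- function(remaining, params, prev_xy = NULL,
                              prev_class = NULL, prev_angle = NULL,
                              ref_class = NULL,
                              s = sqrt(1400^2 + 1050^2),
                              mu_offset = -pi / 2) {
  m <- nrow(remaining)
  if (is.null(m) || m < 1L)
    stop("selection_weights: no remaining targets (contract violation)")
  if (is.null(ref_class))
    ref_class <- min(c(as.character(remaining$item_class),
                       as.character(prev_class)))
  lw <- ifelse(remaining$item_class == ref_class,
               log(params$p_a), log(1 - params$p_a))
  if (!is.null(prev_xy)) {
    if (!is.null(prev_class))
      lw <- lw + ifelse(remaining$item_class == prev_class,
                        log(params$p_s), log(1 - params$p_s))
    d <- sqrt((remaining$x - prev_xy[1])^2 + (remaining$y - prev_xy[2])^2)
    lw <- lw - params$rho_d * d / s
    if (!is.null(prev_angle)) {
      ang <- atan2(remaining$y - prev_xy[2], remaining$x - prev_xy[1])
      mu <- if (params$rho_theta >= 0) 0 else mu_offset
      lw <- lw + abs(params$rho_theta) * cos(wrap_angle(ang - prev_angle) - mu)
    }
  }
  lw <- lw - max(lw)
  w <- exp(lw)
  w / sum(w)
}

#' Simulate a pick sequence from the choice model
#'
#' Draws `n_picks` targets sequentially, without replacement, from a display
#' using [selection_weights()].  The display is treated as static within the
#' sequence; interleaving of item motion between picks is the simulator's
#' job (see [run_agent()]).
#'
#' @param display a display data.frame as from [gen_display()] (columns
#'   `id`, `x`, `y`, `item_class`, `is_target`).
#' @param params a [bias_params()] object.
#' @param n_picks number of targets to collect (at most the number of
#'   targets present).
#' @inheritParams selection_weights
#' @return data.frame of picks in order: `order`, `id`, `x`, `y`,
#'   `item_class`.
#' @export
simulate_sequence <- function(display, params, n_picks,
                              ref_class = NULL, s = NULL,
                              mu_offset = -pi / 2) {
  tg <- display[display$is_target %in% TRUE, , drop = FALSE]
  if (n_picks > nrow(tg))
    stop("n_picks (", n_picks, ") exceeds available targets (", nrow(tg), ")")
  if (is.null(s)) s <- display_diag(display)
  if (is.null(ref_class)) ref_class <- min(as.character(tg$item_class))
  picked <- integer(0)
  prev_xy <- NULL
  prev_class <- NULL
  prev_angle <- NULL
  for (k in seq_len(n_picks)) {
    rem <- tg[!tg$id %in% picked, , drop = FALSE]
    p <- selection_weights(rem, params, prev_xy = prev_xy,
                           prev_class = prev_class,
                           prev_angle = prev_angle,
                           ref_class = ref_class, s = s,
                           mu_offset = mu_offset)
    j <- sample.int(nrow(rem), 1L, prob = p)
    if (!is.null(prev_xy)) {
      dx <- rem$x[j] - prev_xy[1]
      dy <- rem$y[j] - prev_xy[2]
      if (dx != 0 || dy != 0) prev_angle <- atan2(dy, dx)
    }
    prev_xy <- c(rem$x[j], rem$y[j])
    prev_class <- as.character(rem$item_class[j])
    picked <- c(picked, rem$id[j])
  }
  out <- tg[match(picked, tg$id), c("id", "x", "y", "item_class")]
  out <- cbind(order = seq_len(n_picks), out)
  rownames(out) <- NULL
  out
}

display_diag <- function(display) {
  b <- attr(display, "bounds")
  if (is.null(b)) b <- c(1400, 1050)
  sqrt(b[1]^2 + b[2]^2)
}

# Precompute the per-candidate covariates of the sequential likelihood so
# that evaluating it at new parameters is pure vector arithmetic.  One row
# per (step, remaining candidate); geometry is taken from the display
# snapshot each trial carries.
build_choice_table <- function(trials, s, ref_class = NULL) {
  if (!is.null(names(trials)) && "display" %in% names(trials))
    trials <- list(trials)
  all_classes <- unlist(lapply(trials, function(tr) {
    tg <- tr$display[tr$display$is_target %in% TRUE, ]
    as.character(tg$item_class)
  }))
  if (is.null(ref_class)) ref_class <- min(all_classes)
  rows <- vector("list", length(trials))
  step0 <- 0L
  for (ti in seq_along(trials)) {
    tr <- trials[[ti]]
    tg <- tr$display[tr$display$is_target %in% TRUE, , drop = FALSE]
    picks <- tr$picks
    if (!all(picks %in% tg$id))
      stop("trial ", ti, ": pick id(s) not among the display's targets: ",
           paste(utils::head(setdiff(picks, tg$id), 3), collapse = ", "))
    idx <- match(picks, tg$id)
    K <- length(picks)
    parts <- vector("list", K)
    for (k in seq_len(K)) {
      rem <- setdiff(seq_len(nrow(tg)), idx[seq_len(k - 1L)])
      if (!idx[k] %in% rem)
        stop("trial ", ti, ": pick ", k, " repeats an already-picked target")
      m <- length(rem)
      isA <- as.character(tg$item_class[rem]) == ref_class
      same <- rep(FALSE, m)
      dd <- rep(0, m)
      cosd <- rep(0, m)
      sind <- rep(0, m)
      use_sp <- k >= 2L
      use_dir <- FALSE
      if (use_sp) {
        pv <- idx[k - 1L]
        same <- as.character(tg$item_class[rem]) ==
          as.character(tg$item_class[pv])
        dd <- sqrt((tg$x[rem] - tg$x[pv])^2 + (tg$y[rem] - tg$y[pv])^2) / s
        if (k >= 3L) {
          p2 <- idx[k - 2L]
          mx <- tg$x[pv] - tg$x[p2]
          my <- tg$y[pv] - tg$y[p2]
          if (mx != 0 || my != 0) {
            use_dir <- TRUE
            prev_angle <- atan2(my, mx)
            ang <- atan2(tg$y[rem] - tg$y[pv], tg$x[rem] - tg$x[pv])
            dth <- wrap_angle(ang - prev_angle)
            cosd <- cos(dth)
            sind <- sin(dth)
          }
        }
      }
      parts[[k]] <- data.frame(
        step = step0 + k, chosen = rem == idx[k], isA = isA, same = same,
        d = dd, cosd = cosd, sind = sind,
        use_sp = use_sp, use_dir = use_dir)
    }
    step0 <- step0 + K
    rows[[ti]] <- do.call(rbind, parts)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  attr(tab, "ref_class") <- ref_class
  attr(tab, "n_steps") <- step0
  tab
}

# theta = (logit p_a, logit p_s, rho_d, rho_theta); log-weights are linear
# in the covariates so the whole likelihood is three vector ops plus a
# grouped log-sum.
choice_loglik_theta <- function(theta, tab, mu_offset) {
  lpa <- theta[1]; lps <- theta[2]; rd <- theta[3]; rt <- theta[4]
  lw <- ifelse(tab$isA, stats::plogis(lpa, log.p = TRUE),
               stats::plogis(-lpa, log.p = TRUE))
  lw <- lw + tab$use_sp * ifelse(tab$same,
                                 stats::plogis(lps, log.p = TRUE),
                                 stats::plogis(-lps, log.p = TRUE))
  lw <- lw - rd * tab$use_sp * tab$d
  mu <- if (rt >= 0) 0 else mu_offset
  lw <- lw + abs(rt) * tab$use_dir * (tab$cosd * cos(mu) + tab$sind * sin(mu))
  denom <- rowsum(exp(lw), tab$step)
  sum(lw[tab$chosen]) - sum(log(denom))
}

#' Sequential log-likelihood of observed pick sequences
#'
#' Sum over picks of the log-probability that the choice model assigns to
#' the target actually collected, given the targets still remaining at that
#' step.  The last pick of an exhausted display contributes `log(1) = 0`;
#' under neutral parameters a step with `k` remaining targets contributes
#' `log(1/k)`.
#'
#' @param trials one trial or a list of trials, each a list with elements
#'   `display` (a display data.frame, the geometry snapshot) and `picks`
#'   (vector of target ids in collection order).
#' @param params a [bias_params()] object.
#' @param s distance scale (default: display diagonal of the first trial).
#' @param ref_class reference class for `p_a` (default lexicographic first).
#' @param mu_offset see [bias_params()].
#' @return The total log-likelihood (a nonpositive number).
#' @export
bias_loglik <- function(trials, params, s = NULL, ref_class = NULL,
                        mu_offset = -pi / 2) {
  if (!is.null(names(trials)) && "display" %in% names(trials))
    trials <- list(trials)
  if (is.null(s)) s <- display_diag(trials[[1]]$display)
  tab <- build_choice_table(trials, s = s, ref_class = ref_class)
  theta <- c(stats::qlogis(params$p_a), stats::qlogis(params$p_s),
             params$rho_d, params$rho_theta)
  choice_loglik_theta(theta, tab, mu_offset)
}
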