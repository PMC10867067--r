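#' Forager agent policies
#'
#' Constructs the policy a simulated forager uses to pick targets:
#'
#' * `"uniform_random"`: picks a remaining target uniformly at random — the
#'   disorganized regime;
#' * `"scanner_lr"` / `"scanner_tb"`: reading-like sweeps; the display is
#'   divided into vertical (horizontal) bands of `band_width` pixels and the
#'   remaining target earliest in band-then-within-band order is picked —
#'   the organized regime with best-r near 1;
#' * `"spiral"`: picks by increasing angular order around the display
#'   centroid — an organized search that best-r is blind to;
#' * `"bias_model"`: delegates to [selection_weights()] with the supplied
#'   [bias_params()].
#'
#' The quit rule is a fixed pick count (`n_picks`), or leaving when fewer
#' than `min_targets_left` targets remain, whichever comes first — the task
#' is non-exhaustive, so agents may abandon a patch with targets still on
#' screen.
#'
#' @param kind policy name (above).
#' @param n_picks maximum number of targets to collect.
#' @param params [bias_params()] for `kind = "bias_model"`.
#' @param band_width scanner band width in pixels.
#' @param min_targets_left scarcity quit threshold (default 0: quit only by
#'   pick count or exhaustion).
#' @param decision_interval baseline seconds between consecutive picks;
#'   item motion advances by this much before each pick.
#' @param slowdown scarcity exponent on the search time per pick: the
#'   interval before a pick is `decision_interval * (n0 / n_remaining)^slowdown`
#'   with `n0` the initial target count.  Targets get harder to find as the
#'   patch depletes (distractors stay while targets vanish), so time per
#'   target grows; 1 scales it with the inverse remaining-target fraction,
#'   0 turns the slowdown off.
#' @return A classed list `"agent_policy"`.
#' @export
agent_policy <- function(kind = c("uniform_random", "scanner_lr",
                                  "scanner_tb", "spiral", "bias_model"),
                         n_picks = Inf, params = bias_params(),
                         band_width = 140, min_targets_left = 0,
                         decision_interval = 0.7, slowdown = 1) {
  kind <- match.arg(kind)
  structure(list(kind = kind, n_picks = n_picks, params = params,
                 band_width = band_width,
                 min_targets_left = min_targets_left,
                 decision_interval = decision_interval,
                 slowdown = slowdown),
            class = "agent_policy")
}

#' Run a forager agent on a display
#'
#' Interleaves item motion and target picks: before every pick the display
#' advances by the policy's decision interval (targets move at 44 px/s), the
#' policy chooses one remaining target, and the pick-time coordinates are
#' recorded — all organization metrics are computed on coordinates at the
#' moment of collection.  Distractor taps are not simulated (scoring them
#' costs points; agents do not make errors).
#'
#' @param display a [gen_display()] data.frame.
#' @param policy an [agent_policy()].
#' @param motion advance items between picks (`FALSE` freezes the display,
#'   useful for likelihood-exact choice-model studies).
#' @return data.frame of picks: `order`, `id`, `x`, `y`, `t`, `item_class`,
#'   `is_target`; attribute `quit_reason` is `"pick_count"`, `"scarcity"`,
#'   or `"exhausted"`.
#' @export
run_agent <- function(display, policy, motion = TRUE) {
  stopifnot(inherits(policy, "agent_policy"))
  s <- display_diag(display)
  tg0 <- display[display$is_target %in% TRUE, , drop = FALSE]
  ref_class <- if (nrow(tg0)) min(as.character(tg0$item_class)) else NA
  centroid <- c(mean(tg0$x), mean(tg0$y))
  picks <- list()
  prev_xy <- NULL
  prev_class <- NULL
  prev_angle <- NULL
  itinerary <- NULL  # planned sweep for scanner policies
  quit_reason <- "pick_count"
  k <- 0L
  n_t0 <- max(1L, nrow(tg0))
  while (k < policy$n_picks) {
    rem <- display[display$is_target %in% TRUE, , drop = FALSE]
    if (nrow(rem) == 0L) { quit_reason <- "exhausted"; break }
    if (nrow(rem) <= policy$min_targets_left) {
      quit_reason <- "scarcity"; break
    }
    j <- switch(policy$kind,
      uniform_random = sample.int(nrow(rem), 1L),
      scanner_lr = ,
      scanner_tb = ,
      spiral = {
        # organized agents plan a whole-display sweep over the targets they
        # will collect (planned once, on first-pick positions), then follow
        # it: scanners sweep bands along one axis, the spiral sweeps
        # angularly around the centroid
        if (is.null(itinerary)) {
          m <- nrow(rem)
          npk <- min(policy$n_picks, m)
          along <- switch(policy$kind,
            scanner_lr = rem$x,
            scanner_tb = rem$y,
            spiral = {
              ang <- atan2(rem$y - centroid[2], rem$x - centroid[1])
              (ang - stats::runif(1, 0, 2 * pi)) %% (2 * pi)
            })
          # a sweep at a regular pace: collect, at each of npk evenly
          # spaced sweep positions, the nearest not-yet-claimed target
          grid <- seq(min(along), max(along), length.out = npk)
          chosen <- integer(0)
          for (g in grid) {
            dist_g <- abs(along - g)
            dist_g[chosen] <- Inf
            chosen <- c(chosen, which.min(dist_g))
          }
          itinerary <- rem$id[chosen[order(along[chosen])]]
        }
        nxt <- itinerary[itinerary %in% rem$id][1L]
        if (is.na(nxt)) nxt <- rem$id[1L]
        which(rem$id == nxt)
      },
      bias_model = {
        p <- selection_weights(rem, policy$params, prev_xy = prev_xy,
                               prev_class = prev_class,
                               prev_angle = prev_angle,
                               ref_class = ref_class, s = s)
        sample.int(nrow(rem), 1L, prob = p)
      })
    k <- k + 1L
    # the chosen target is pursued and tapped while items keep moving:
    # search-plus-reach time scales with target scarcity, and the recorded
    # pick-time coordinates are the positions at the moment of the tap
    if (motion) {
      n_now <- max(1L, nrow(rem))
      dt <- policy$decision_interval * (n_t0 / n_now)^policy$slowdown
      display <- step_motion(display, dt)
      rem_now <- display[display$is_target %in% TRUE, , drop = FALSE]
      j <- which(rem_now$id == rem$id[j])
      rem <- rem_now
    }
    row <- rem[j, , drop = FALSE]
    if (!is.null(prev_xy)) {
      dx <- row$x - prev_xy[1]; dy <- row$y - prev_xy[2]
      if (dx != 0 || dy != 0) prev_angle <- atan2(dy, dx)
    }
    prev_xy <- c(row$x, row$y)
    prev_class <- as.character(row$item_class)
    picks[[k]] <- data.frame(order = k, id = row$id, x = row$x, y = row$y,
                             t = attr(display, "time"),
                             item_class = row$item_class, is_target = TRUE,
                             stringsAsFactors = FALSE)
    display <- display[display$id != row$id, , drop = FALSE]
  }
  out <- if (length(picks)) do.call(rbind, picks) else
    data.frame(order = integer(0), id = integer(0), x = numeric(0),
               y = numeric(0), t = numeric(0), item_class = character(0),
               is_target = logical(0))
  rownames(out) <- NULL
  attr(out, "quit_reason") <- quit_reason
  out
}

#' Generate a lifespan-style synthetic cohort
#'
#' Simulates a cohort of participants aged 4-25 years foraging with the
#' choice model, with bias parameters that drift with the natural log of
#' age: the proximity bias `rho_d` of participant `i` is
#' `max(0, rho_d_intercept + rho_d_slope * ln(age_i) + noise)`, so a
#' positive slope makes older foragers pick nearer targets (the organized
#' end of the spectrum), while `rho_d_slope = 0` gives a null cohort.
#' Depletion within a trial (targets thin out while distractors stay) and
#' its bin-2 disorganization are emergent, not injected.
#'
#' @param n_participants number of participants; ages are sampled uniformly
#'   on `[4, 25]` unless `ages` is given.
#' @param ages optional explicit age vector (length `n_participants`).
#' @param trials_per_condition patches visited per condition.
#' @param set_sizes item counts sampled per trial.
#' @param conditions conditions each participant runs.
#' @param rho_d_intercept,rho_d_slope,rho_d_sd the ln-age drift of the
#'   proximity bias.
#' @param p_a,p_s,rho_theta_sd remaining generative parameters (`rho_theta`
#'   is drawn per participant from `N(0, rho_theta_sd)`).
#' @param quit_frac fraction of a display's targets collected before
#'   leaving (non-exhaustive foraging).
#' @param n_target_classes see [gen_display()].
#' @param motion advance items between picks.
#' @return List: `trials` (a [forage_trials()] log), `truth` (one row per
#'   participant x condition with the generating parameters), `displays`
#'   (list of the generated displays keyed by participant/condition/trial),
#'   and `choice_data` (per participant x condition, the display/pick pairs
#'   in the form [fit_bias()] consumes).
#' @export
gen_lifespan_dataset <- function(n_participants = 40, ages = NULL,
                                 trials_per_condition = 2,
                                 set_sizes = c(60, 100, 140, 180),
                                 conditions = c("feature", "conjunction"),
                                 rho_d_intercept = 0, rho_d_slope = 1,
                                 rho_d_sd = 0.3, p_a = 0.5, p_s = 0.6,
                                 rho_theta_sd = 0.3, quit_frac = 0.6,
                                 n_target_classes = 1L, motion = TRUE) {
  if (is.null(ages)) ages <- stats::runif(n_participants, 4, 25)
  stopifnot(length(ages) == n_participants)
  rows <- list()
  truth <- list()
  displays <- list()
  choice_data <- list()
  for (i in seq_len(n_participants)) {
    pid <- sprintf("p%03d", i)
    for (cond in conditions) {
      rho_d_i <- max(0, rho_d_intercept + rho_d_slope * log(ages[i]) +
                       stats::rnorm(1, 0, rho_d_sd))
      rt_i <- stats::rnorm(1, 0, rho_theta_sd)
      pars <- bias_params(p_a = p_a, p_s = p_s, rho_d = rho_d_i,
                          rho_theta = rt_i)
      truth[[length(truth) + 1L]] <- data.frame(
        participant = pid, age = ages[i], condition = cond,
        p_a = p_a, p_s = p_s, rho_d = rho_d_i, rho_theta = rt_i,
        stringsAsFactors = FALSE)
      for (tr in seq_len(trials_per_condition)) {
        ss <- sample(set_sizes, 1)
        disp <- gen_display(ss, cond, n_target_classes = n_target_classes)
        n_t <- sum(disp$is_target)
        pol <- agent_policy("bias_model",
                            n_picks = max(2L, round(quit_frac * n_t)),
                            params = pars)
        pk <- run_agent(disp, pol, motion = motion)
        key <- paste(pid, cond, tr, sep = "/")
        displays[[key]] <- disp
        if (nrow(pk) == 0L) next
        ckey <- paste(pid, cond, sep = "/")
        choice_data[[ckey]] <- c(choice_data[[ckey]],
                                 list(list(display = disp, picks = pk$id)))
        rows[[length(rows) + 1L]] <- data.frame(
          participant = pid, age = ages[i], condition = cond,
          set_size = ss, trial = tr, order = pk$order, x = pk$x, y = pk$y,
          t = pk$t, item_class = pk$item_class, is_target = TRUE,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(trials = forage_trials(do.call(rbind, rows)),
       truth = do.call(rbind, truth),
       displays = displays,
       choice_data = choice_data)
}
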