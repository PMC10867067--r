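#' Generate a foraging display
#'
#' Creates one display of the dynamic foraging task: `set_size` items at
#' uniform random positions on a 1400 x 1050 px screen, a target proportion
#' drawn uniformly between 20% and 30%, and item classes according to the
#' condition.  In the feature condition items are colored squares (four
#' colors, one of which is the target color); in the conjunction condition
#' items are colored shapes (two colors x two shapes, one cell being the
#' target conjunction).  Every item gets a motion heading uniform on
#' `[0, 2*pi)` and a time to its next pseudo-random direction change.
#'
#' `n_target_classes = 2` splits the targets into two subtypes (suffixes
#' `".a"`/`".b"`); displays generated this way are the test bed for the
#' class-preference and stickiness parameters of the choice model, which
#' are unidentifiable when all targets share one class.
#'
#' `layout = "ring"` places items on an annulus around the display center
#' instead of uniformly; such displays exercise spiral-like searches, the
#' known blind spot of the best-r indicator.
#'
#' @param set_size number of items (the task uses 60, 100, 140, 180).
#' @param condition `"feature"` or `"conjunction"`.
#' @param n_target_classes 1 (task-faithful) or 2 (choice-model test bed).
#' @param bounds display size in pixels, `c(width, height)`.
#' @param layout `"uniform"` or `"ring"`.
#' @param turn_mean mean of the exponential time between direction changes
#'   (seconds).
#' @return data.frame with one row per item (`id`, `item_class`,
#'   `is_target`, `x`, `y`, `heading`, `t_next_turn`) and attributes
#'   `bounds`, `condition`, `set_size`, `time`, `turn_mean`.
#' @export
gen_display <- function(set_size, condition = c("feature", "conjunction"),
                        n_target_classes = 1L, bounds = c(1400, 1050),
                        layout = c("uniform", "ring"), turn_mean = 1) {
  condition <- match.arg(condition)
  layout <- match.arg(layout)
  stopifnot(set_size >= 2)
  frac <- stats::runif(1, 0.20, 0.30)
  n_t <- round(frac * set_size)
  n_t <- min(max(n_t, ceiling(0.20 * set_size)), floor(0.30 * set_size))
  n_d <- set_size - n_t
  classes <- if (condition == "feature") {
    cols <- c("blue", "green", "red", "yellow")
    tgt <- sample(cols, 1)
    c(rep(tgt, n_t), sample(setdiff(cols, tgt), n_d, replace = TRUE))
  } else {
    cells <- c("blue-circle", "blue-square", "green-circle", "green-square")
    tgt <- sample(cells, 1)
    c(rep(tgt, n_t), sample(setdiff(cells, tgt), n_d, replace = TRUE))
  }
  is_target <- rep(c(TRUE, FALSE), c(n_t, n_d))
  if (n_target_classes == 2L) {
    sub <- sample(rep(c(".a", ".b"), length.out = n_t))
    classes[seq_len(n_t)] <- paste0(classes[seq_len(n_t)], sub)
  }
  if (layout == "uniform") {
    x <- stats::runif(set_size, 0, bounds[1])
    y <- stats::runif(set_size, 0, bounds[2])
  } else {
    r0 <- 0.35 * min(bounds)
    r <- r0 + stats::runif(set_size, -0.06, 0.06) * min(bounds)
    th <- stats::runif(set_size, 0, 2 * pi)
    x <- pmin(pmax(bounds[1] / 2 + r * cos(th), 0), bounds[1])
    y <- pmin(pmax(bounds[2] / 2 + r * sin(th), 0), bounds[2])
  }
  d <- data.frame(id = seq_len(set_size), item_class = classes,
                  is_target = is_target, x = x, y = y,
                  heading = stats::runif(set_size, 0, 2 * pi),
                  t_next_turn = stats::rexp(set_size, 1 / turn_mean),
                  stringsAsFactors = FALSE)
  attr(d, "bounds") <- bounds
  attr(d, "condition") <- condition
  attr(d, "set_size") <- set_size
  attr(d, "time") <- 0
  attr(d, "turn_mean") <- turn_mean
  d
}

#' Advance item motion by one time step
#'
#' Every item moves `speed * dt` pixels along its heading (44 px/s in the
#' task).  Headings are redrawn at exponentially distributed intervals
#' (mean `turn_mean`, checked at step granularity), and items reflect off
#' the display edges, which preserves the distance traveled and keeps the
#' spatial density uniform.
#'
#' @param display a [gen_display()] data.frame.
#' @param dt step duration in seconds (> 0).
#' @param speed item speed in px/s.
#' @return The advanced display (same structure, `time` attribute moved
#'   forward by `dt`).
#' @export
step_motion <- function(display, dt, speed = 44) {
  stopifnot(dt > 0)
  bounds <- attr(display, "bounds")
  turn_mean <- attr(display, "turn_mean")
  if (is.null(turn_mean)) turn_mean <- 1
  n <- nrow(display)
  if (n) {
    turn <- display$t_next_turn <= 0
    if (any(turn)) {
      display$heading[turn] <- stats::runif(sum(turn), 0, 2 * pi)
      display$t_next_turn[turn] <- stats::rexp(sum(turn), 1 / turn_mean)
    }
    display$t_next_turn <- display$t_next_turn - dt
    x <- display$x + cos(display$heading) * speed * dt
    y <- display$y + sin(display$heading) * speed * dt
    hx <- cos(display$heading)
    hy <- sin(display$heading)
    for (pass in 1:10) {
      ox <- x < 0 | x > bounds[1]
      oy <- y < 0 | y > bounds[2]
      if (!any(ox | oy)) break
      x[x < 0] <- -x[x < 0]
      x[x > bounds[1]] <- 2 * bounds[1] - x[x > bounds[1]]
      y[y < 0] <- -y[y < 0]
      y[y > bounds[2]] <- 2 * bounds[2] - y[y > bounds[2]]
      hx[ox] <- -hx[ox]
      hy[oy] <- -hy[oy]
    }
    display$x <- x
    display$y <- y
    display$heading <- atan2(hy, hx)
  }
  attr(display, "time") <- attr(display, "time") + dt
  display
}

#' Simulate a balanced score table from one candidate model's structure
#'
#' Generates a long score table (participant x condition x set size x bin)
#' whose response follows exactly the fixed-effect structure of one of the
#' ten candidate models ([candidate_models()]) plus a Gaussian random
#' participant intercept and residual noise.  This is the ground truth for
#' generator-selector consistency checks: selection over the ten candidates
#' should assign the minimum AICc to the generating structure most of the
#' time.
#'
#' Default effect sizes are moderate on a unit residual scale
#' (`sigma_e = 1`, `sigma_u = 0.5`) with slopes scaled to the natural
#' predictor ranges (ln-age 1.4-3.2, set size 60-180).
#'
#' @param model_id generating structure, 1..10.
#' @param n_participants number of simulated participants (ages uniform on
#'   4-25 years).
#' @param beta named fixed-effect vector over the model's design columns
#'   (defaults supplied for any candidate).
#' @param sigma_u random-intercept standard deviation.
#' @param sigma_e residual standard deviation.
#' @return data.frame: `participant`, `age`, `log_age`, `condition`,
#'   `set_size`, `bin`, `score`.
#' @export
simulate_score_table <- function(model_id, n_participants = 279,
                                 beta = NULL, sigma_u = 0.5, sigma_e = 1) {
  terms <- candidate_models(model_id)
  defaults <- c("(Intercept)" = 0, log_age = 0.3, condition = 0.4,
                set_size = 0.004, bin = 0.3,
                "log_age:set_size" = 0.006, "condition:set_size" = 0.005,
                "log_age:bin" = 0.2, "bin:condition" = 0.3,
                "condition:bin" = 0.3,
                "log_age:set_size:condition" = 0.006,
                "log_age:set_size:condition:bin" = 0.008)
  if (is.null(beta)) beta <- defaults[c("(Intercept)", terms)]
  age <- stats::runif(n_participants, 4, 25)
  grid <- expand.grid(condition = c("feature", "conjunction"),
                      set_size = c(60, 100, 140, 180),
                      bin = c("bin1", "bin2"),
                      participant = sprintf("p%03d", seq_len(n_participants)),
                      stringsAsFactors = FALSE)
  grid$age <- age[match(grid$participant,
                        sprintf("p%03d", seq_len(n_participants)))]
  grid$log_age <- log(grid$age)
  des <- build_design(model_id, grid, response = "set_size")  # X only
  u <- stats::rnorm(n_participants, 0, sigma_u)
  names(u) <- sprintf("p%03d", seq_len(n_participants))
  grid$score <- as.numeric(des$X %*% beta) + u[grid$participant] +
    stats::rnorm(nrow(grid), 0, sigma_e)
  grid[, c("participant", "age", "log_age", "condition", "set_size",
           "bin", "score")]
}
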