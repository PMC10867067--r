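test_that("generated displays respect set size, bounds, and target fraction", {
  set.seed(601)
  for (i in 1:400) {
    ss <- sample(c(60, 100, 140, 180), 1)
    d <- gen_display(ss, sample(c("feature", "conjunction"), 1))
    expect_equal(nrow(d), ss)
    nt <- sum(d$is_target)
    expect_gte(nt, ceiling(0.20 * ss))
    expect_lte(nt, floor(0.30 * ss))
    expect_true(all(d$x >= 0 & d$x <= 1400 & d$y >= 0 & d$y <= 1050))
  }
})

test_that("displays are reproducible under a fixed seed", {
  set.seed(602)
  d1 <- gen_display(60, "conjunction")
  set.seed(602)
  d2 <- gen_display(60, "conjunction")
  expect_identical(d1, d2)
})

test_that("conjunction displays have one target cell among the four color-shape cells", {
  set.seed(603)
  d <- gen_display(100, "conjunction")
  tgt_classes <- unique(d$item_class[d$is_target])
  expect_length(tgt_classes, 1)
  expect_match(tgt_classes, "^(blue|green)-(circle|square)$")
  expect_false(tgt_classes %in% d$item_class[!d$is_target])
  # two-subtype option splits the target class for choice-model work
  d2 <- gen_display(100, "conjunction", n_target_classes = 2)
  expect_length(unique(d2$item_class[d2$is_target]), 2)
})

test_that("items travel exactly speed * dt and reflect off the walls", {
  set.seed(604)
  d <- gen_display(100, "feature", turn_mean = 1e9)  # no direction changes
  d1 <- step_motion(d, 1)
  trav <- sqrt((d1$x - d$x)^2 + (d1$y - d$y)^2)
  interior <- d$x > 44 & d$x < 1356 & d$y > 44 & d$y < 1006
  expect_equal(trav[interior], rep(44, sum(interior)), tolerance = 1e-9)
  dq <- step_motion(d, 0.25)
  travq <- sqrt((dq$x - d$x)^2 + (dq$y - d$y)^2)
  expect_equal(travq[interior], rep(11, sum(interior)), tolerance = 1e-9)
  # an item aimed at the wall reflects and stays inside
  dw <- d[1, ]
  dw$x <- 2; dw$y <- 500; dw$heading <- pi  # heading straight left
  attr(dw, "bounds") <- c(1400, 1050); attr(dw, "time") <- 0
  dw1 <- step_motion(dw, 1)
  expect_equal(dw1$x, 42)  # 2 px to the wall, 42 back out
  expect_gte(dw1$x, 0)
  # long horizon: everything stays in bounds
  dd <- d
  for (i in 1:30) dd <- step_motion(dd, 1)
  expect_true(all(dd$x >= 0 & dd$x <= 1400 & dd$y >= 0 & dd$y <= 1050))
  expect_equal(attr(dd, "time"), 30)
})

test_that("agent regimes separate: scanners organized, random disorganized, spiral the blind spot", {
  set.seed(605)
  sc <- replicate(25, {
    d <- gen_display(sample(c(100, 140, 180), 1), "feature")
    pk <- run_agent(d, agent_policy("scanner_lr", n_picks = 12),
                    motion = FALSE)
    best_r(pk$x, pk$y)
  })
  tb <- replicate(25, {
    d <- gen_display(sample(c(100, 140, 180), 1), "feature")
    pk <- run_agent(d, agent_policy("scanner_tb", n_picks = 12),
                    motion = FALSE)
    best_r(pk$x, pk$y)
  })
  rnd <- replicate(200, {
    d <- gen_display(sample(c(100, 140, 180), 1), "feature")
    pk <- run_agent(d, agent_policy("uniform_random", n_picks = 12),
                    motion = FALSE)
    best_r(pk$x, pk$y)
  })
  expect_true(all(sc >= 0.95))
  expect_true(all(tb >= 0.95))
  expect_lt(mean(rnd), 0.5)
  expect_lt(max(rnd), min(sc))  # full separation at this scale
  # spiral on ring displays: organized path (low PAO) that best-r misses
  sp <- replicate(30, {
    d <- gen_display(100, "feature", layout = "ring")
    pk <- run_agent(d, agent_policy("spiral", n_picks = 12), motion = FALSE)
    c(best_r(pk$x, pk$y), pao(pk$x, pk$y))
  })
  expect_lt(mean(sp[1, ]), 0.85)
  expect_lt(mean(sp[2, ]), 25)
  expect_lt(mean(sp[1, ]), mean(sc))
})

test_that("agents honor quit rules and record pick-time coordinates", {
  set.seed(606)
  d <- gen_display(60, "feature")
  nt <- sum(d$is_target)
  pk <- run_agent(d, agent_policy("uniform_random", n_picks = nt + 10))
  expect_equal(nrow(pk), nt)
  expect_identical(attr(pk, "quit_reason"), "exhausted")
  pk2 <- run_agent(d, agent_policy("uniform_random", n_picks = 5))
  expect_equal(nrow(pk2), 5)
  expect_identical(attr(pk2, "quit_reason"), "pick_count")
  pk3 <- run_agent(d, agent_policy("uniform_random",
                                   min_targets_left = nt - 3))
  expect_equal(nrow(pk3), 3)
  expect_identical(attr(pk3, "quit_reason"), "scarcity")
  # with motion on, pick times increase and coordinates stay in bounds
  expect_true(all(diff(pk$t) > 0))
  expect_true(all(pk$x >= 0 & pk$x <= 1400 & pk$y >= 0 & pk$y <= 1050))
})

test_that("lifespan cohorts have the requested age structure and drift", {
  set.seed(607)
  ages <- rep(4:25, each = 2)
  ls <- gen_lifespan_dataset(n_participants = length(ages), ages = ages,
                             trials_per_condition = 1,
                             conditions = "feature")
  expect_equal(nrow(ls$truth), length(ages))
  expect_true(all(table(floor(ls$truth$age)) >= 2))
  expect_s3_class(ls$trials, "forage_trials")
  # positive ln-age slope: generated rho_d grows with age
  expect_gt(cor(log(ls$truth$age), ls$truth$rho_d), 0.5)
  # zero slope: no drift in the generating parameters
  set.seed(608)
  ls0 <- gen_lifespan_dataset(n_participants = 30, trials_per_condition = 1,
                              rho_d_slope = 0, rho_d_intercept = 2,
                              conditions = "feature")
  expect_lt(abs(cor(log(ls0$truth$age), ls0$truth$rho_d)), 0.5)
})

test_that("a null age effect in the generator yields a null fitted age coefficient", {
  set.seed(609)
  ls <- gen_lifespan_dataset(n_participants = 30, trials_per_condition = 2,
                             rho_d_slope = 0, rho_d_intercept = 3,
                             quit_frac = 0.8)
  res <- build_score_table(ls$trials)
  fit <- fit_candidates(res$scores, "mean_itd", models = 1)$model1
  est <- lme4::fixef(fit$fit)[["log_age"]]
  se <- sqrt(diag(as.matrix(vcov(fit$fit))))[[2]]
  expect_lt(abs(est / se), 2)
})

test_that("older simulated foragers recover larger proximity biases", {
  set.seed(610)
  ages <- seq(4, 25, length.out = 14)
  rho_hat <- sapply(ages, function(a) {
    rho_d_i <- max(0, 1 * log(a))
    trials <- lapply(1:10, function(i) {
      d <- gen_display(100, "feature", n_target_classes = 2)
      list(display = d,
           picks = simulate_sequence(d, bias_params(rho_d = rho_d_i), 14)$id)
    })
    unname(coef(fit_bias(trials))["rho_d"])
  })
  expect_gt(cor(log(ages), rho_hat), 0.5)
})
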