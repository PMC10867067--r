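rem2 <- function(x, y, cls) data.frame(x = x, y = y, item_class = cls,
                                       stringsAsFactors = FALSE)

test_that("neutral parameters give a uniform distribution over remaining targets", {
  rem <- rem2(c(0, 100, 700, 900), c(0, 50, 600, 20), c("A", "B", "A", "B"))
  p <- selection_weights(rem, bias_params(), prev_xy = c(5, 5),
                         prev_class = "A", prev_angle = 0.3, ref_class = "A")
  expect_equal(p, rep(0.25, 4))
  expect_equal(sum(p), 1)
})

test_that("a strong proximity bias concentrates mass on the nearest target", {
  rem <- rem2(c(10, 400, 900), c(0, 0, 0), rep("A", 3))
  p <- selection_weights(rem, bias_params(rho_d = 500), prev_xy = c(0, 0),
                         prev_class = "A", ref_class = "A", s = 1750)
  expect_gt(p[1], 0.999)
})

test_that("class and stickiness weights combine by the product rule", {
  # after an A pick, candidates A and B with p_a = .7, p_s = .6, spatial off:
  # P(A) = .7*.6 / (.7*.6 + .3*.4) = 0.7777...
  rem <- rem2(c(0, 0), c(0, 0), c("A", "B"))
  p <- selection_weights(rem, bias_params(p_a = 0.7, p_s = 0.6),
                         prev_xy = c(0, 0), prev_class = "A",
                         ref_class = "A")
  expect_equal(p[1], 0.42 / 0.54, tolerance = 1e-12)
})

test_that("weights are invariant under candidate relabeling and sum to one", {
  set.seed(401)
  rem <- rem2(runif(8, 0, 1400), runif(8, 0, 1050),
              sample(c("A", "B"), 8, TRUE))
  pars <- bias_params(0.6, 0.7, 2, -1)
  p <- selection_weights(rem, pars, prev_xy = c(700, 500), prev_class = "B",
                         prev_angle = 1, ref_class = "A")
  expect_equal(sum(p), 1)
  perm <- sample(8)
  p2 <- selection_weights(rem[perm, ], pars, prev_xy = c(700, 500),
                          prev_class = "B", prev_angle = 1, ref_class = "A")
  expect_equal(p2, p[perm])
})

test_that("simulate_sequence is reproducible under a fixed seed and depletes without replacement", {
  set.seed(402)
  d <- gen_display(100, "feature", n_target_classes = 2)
  set.seed(7)
  s1 <- simulate_sequence(d, bias_params(), 12)
  set.seed(7)
  s2 <- simulate_sequence(d, bias_params(), 12)
  expect_identical(s1, s2)
  expect_equal(anyDuplicated(s1$id), 0)
  expect_error(simulate_sequence(d, bias_params(), sum(d$is_target) + 1),
               "exceeds")
})

test_that("proximity bias shortens realized intertarget distances", {
  set.seed(403)
  d <- gen_display(100, "feature")
  itd <- function(pars) mean(replicate(200, {
    sq <- simulate_sequence(d, pars, 10)
    mean_itd(sq$x, sq$y)
  }))
  expect_lt(itd(bias_params(rho_d = 8)), itd(bias_params()))
})

test_that("stickiness lengthens same-class runs", {
  run_len <- function(cls) mean(rle(cls)$lengths)
  set.seed(404)
  d <- gen_display(100, "feature", n_target_classes = 2)
  rl <- function(ps) mean(replicate(200, {
    sq <- simulate_sequence(d, bias_params(p_s = ps), 12)
    run_len(as.character(sq$item_class))
  }))
  expect_gt(rl(0.95), rl(0.5))
})

test_that("log-likelihood matches the sampling-without-replacement structure", {
  # single remaining target: the final step is forced, contributing log(1)
  d <- data.frame(id = 1:2, item_class = c("A", "B"), is_target = TRUE,
                  x = c(0, 500), y = c(0, 0))
  ll_both <- bias_loglik(list(display = d, picks = c(1, 2)), bias_params())
  expect_equal(ll_both, log(1 / 2) + log(1))
  # neutral parameters: step with k remaining contributes log(1/k)
  set.seed(405)
  d4 <- gen_display(60, "feature", n_target_classes = 2)
  nt <- sum(d4$is_target)
  sq <- simulate_sequence(d4, bias_params(), 5)
  ll <- bias_loglik(list(display = d4, picks = sq$id), bias_params())
  expect_equal(ll, sum(log(1 / (nt - 0:4))))
  # unknown pick ids are a data-consistency error
  expect_error(bias_loglik(list(display = d4, picks = c(99999)),
                           bias_params()), "not among")
})

test_that("likelihood is invariant under rigid motions of display and picks", {
  set.seed(406)
  d <- gen_display(80, "conjunction", n_target_classes = 2)
  sq <- simulate_sequence(d, bias_params(0.6, 0.7, 3, 1), 10)
  pars <- bias_params(0.55, 0.65, 2, -0.8)
  ll <- bias_loglik(list(display = d, picks = sq$id), pars, s = 1750)
  th <- 1.1
  dr <- d
  dr$x <- cos(th) * d$x - sin(th) * d$y + 400
  dr$y <- sin(th) * d$x + cos(th) * d$y - 150
  llr <- bias_loglik(list(display = dr, picks = sq$id), pars, s = 1750)
  expect_equal(llr, ll, tolerance = 1e-9)
})

test_that("the generating parameters beat perturbed ones on average", {
  set.seed(407)
  truth <- bias_params(0.6, 0.65, 2, 0)
  trials <- lapply(1:60, function(i) {
    d <- gen_display(100, "feature", n_target_classes = 2)
    list(display = d, picks = simulate_sequence(d, truth, 12)$id)
  })
  ll_truth <- bias_loglik(trials, truth)
  ll_pert <- bias_loglik(trials, bias_params(0.3, 0.3, 8, 3))
  expect_gt(ll_truth, ll_pert)
})

test_that("with spatial terms off, p_a matches the class-pick frequency on balanced bags", {
  # large balanced bags keep the remaining class counts nearly equal, where
  # the sequential choice probability reduces to p_a itself
  set.seed(408)
  n <- 1000  # deep bag: remaining class counts stay essentially balanced
  d <- data.frame(id = 1:n, item_class = rep(c("A", "B"), n / 2),
                  is_target = TRUE, x = runif(n), y = runif(n))
  truth <- bias_params(p_a = 0.7, p_s = 0.5)
  trials <- lapply(1:30, function(i)
    list(display = d, picks = simulate_sequence(d, truth, 6)$id))
  freq_A <- mean(unlist(lapply(trials, function(tr)
    d$item_class[match(tr$picks, d$id)] == "A")))
  fit <- fit_bias(trials, starts = rbind(c(0, 0, 0, 0)))
  expect_equal(unname(coef(fit)["p_a"]), freq_A, tolerance = 0.01)
})

test_that("single-class data flags p_a and p_s as unidentifiable", {
  set.seed(409)
  d <- gen_display(60, "feature")  # all targets share one class
  trials <- list(list(display = d,
                      picks = simulate_sequence(d, bias_params(), 8)$id))
  fit <- fit_bias(trials)
  expect_false(fit$identifiable[["p_a"]])
  expect_false(fit$identifiable[["p_s"]])
  expect_equal(unname(coef(fit)[c("p_a", "p_s")]), c(0.5, 0.5))
  expect_true(all(is.na(fit$se[c("p_a", "p_s")])))
})

test_that("parameter recovery is monotone in the true proximity bias", {
  set.seed(410)
  est <- sapply(c(0, 2, 6), function(rd) {
    fits <- replicate(8, {
      trials <- lapply(1:25, function(i) {
        d <- gen_display(100, "feature", n_target_classes = 2)
        list(display = d,
             picks = simulate_sequence(d, bias_params(rho_d = rd), 10)$id)
      })
      unname(coef(fit_bias(trials))["rho_d"])
    })
    mean(fits)
  })
  expect_true(all(diff(est) > 0))
})

test_that("bias_fit methods expose estimates, likelihood, and simulation", {
  set.seed(411)
  d <- gen_display(100, "feature", n_target_classes = 2)
  trials <- lapply(1:20, function(i)
    list(display = d,
         picks = simulate_sequence(d, bias_params(rho_d = 2), 10)$id))
  fit <- fit_bias(trials)
  expect_s3_class(fit, "bias_fit")
  expect_named(coef(fit), c("p_a", "p_s", "rho_d", "rho_theta",
                            "abs_rho_theta"))
  expect_equal(coef(fit)[["abs_rho_theta"]], abs(coef(fit)[["rho_theta"]]))
  expect_lt(as.numeric(logLik(fit)), 0)
  # reported logLik is reproducible from the public likelihood
  expect_equal(as.numeric(logLik(fit)),
               bias_loglik(trials, fit$params, s = fit$s), tolerance = 1e-6)
  sm <- summary(fit)
  expect_equal(rownames(sm), c("p_a", "p_s", "rho_d", "rho_theta"))
  sims <- simulate(fit, nsim = 2, seed = 1, display = d, n_picks = 6)
  expect_length(sims, 2)
  expect_equal(nrow(sims[[1]]), 6)
  expect_output(print(fit), "choice model")
})
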