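#' Fit the target-choice bias model by maximum likelihood
#'
#' Estimates the four bias parameters of the sampling-without-replacement
#' choice model ([bias_params()]) from observed pick sequences, by
#' maximizing the sequential likelihood over `(logit p_a, logit p_s, rho_d,
#' rho_theta)` with a quasi-Newton search (`L-BFGS-B`, `rho_d` bounded below
#' by 0) from a small multistart grid.  Standard errors come from the
#' observed information (numerical Hessian) at the optimum, delta-method
#' transformed to the natural scale for `p_a` and `p_s`.
#'
#' Parameters that the data cannot identify are flagged rather than
#' guessed: if every candidate ever on offer belongs to one class, `p_a`
#' (and `p_s`) drop out of the likelihood and are reported at 0.5 with `NA`
#' standard errors.
#'
#' @param trials a list of trials, each a list with `display` (display
#'   data.frame: the geometry the choices were made over) and `picks`
#'   (target ids in collection order); a single such list is also accepted.
#' @param s distance standardization scale in pixels (default: the display
#'   diagonal of the first trial).
#' @param ref_class reference class "A" for the preference parameter;
#'   default: lexicographically first target class in the data (recorded in
#'   the fit).
#' @param mu_offset preferred angular offset for negative `rho_theta`
#'   (default `-pi/2`).
#' @param starts optional matrix of starting values (columns: logit p_a,
#'   logit p_s, rho_d, rho_theta); a default 6-point grid is used otherwise.
#' @return An object of class `"bias_fit"`: see [coef.bias_fit()],
#'   [summary.bias_fit()], [logLik.bias_fit()], [vcov.bias_fit()],
#'   [simulate.bias_fit()].
#' @examples
#' set.seed(1)
#' d <- gen_display(60, "feature", n_target_classes = 2)
#' tr <- list(display = d,
#'            picks = simulate_sequence(d, bias_params(rho_d = 3), 10)$id)
#' fit <- fit_bias(list(tr))
#' coef(fit)
#' @export
fit_bias <- function(trials, s = NULL, ref_class = NULL,
                     mu_offset = -pi / 2, starts = NULL) {
  if (!is.null(names(trials)) && "display" %in% names(trials))
    trials <- list(trials)
  stopifnot(length(trials) >= 1L)
  if (is.null(s)) s <- display_diag(trials[[1]]$display)
  tab <- build_choice_table(trials, s = s, ref_class = ref_class)
  ref_class <- attr(tab, "ref_class")

  # a term is identifiable only if its covariate varies WITHIN some choice
  # step: per-step constants cancel in the normalization
  varies_within <- function(v, steps)
    any(tapply(v, steps, function(z) max(z) > min(z)))
  id_pa <- varies_within(tab$isA, tab$step)
  id_ps <- any(tab$use_sp) &&
    varies_within(tab$same[tab$use_sp], tab$step[tab$use_sp])
  id_rd <- any(tab$use_sp) &&
    varies_within(tab$d[tab$use_sp], tab$step[tab$use_sp])
  id_rt <- any(tab$use_dir)

  free <- c(id_pa, id_ps, id_rd, id_rt)
  if (!any(free)) stop("fit_bias: no identifiable parameters in the data")
  expand <- function(th_free) {
    th <- c(0, 0, 0, 0)  # unidentifiable coordinates pinned at neutrality
    th[free] <- th_free
    th
  }
  negll <- function(th_free)
    -choice_loglik_theta(expand(th_free), tab, mu_offset)
  if (is.null(starts))
    starts <- rbind(c(0, 0, 0.5,  0.5),
                    c(0, 0, 0.5, -0.5),
                    c(0, 0, 3,    0.1),
                    c(0, 0, 3,   -0.1),
                    c(0.5, 0.5, 0, 1),
                    c(-0.5, -0.5, 1, -1))
  lower <- c(-12, -12, 0, -50)[free]
  upper <- c(12, 12, 60, 50)[free]

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[i, free], negll, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("fit_bias: all optimizer starts failed")

  theta <- expand(best$par)
  se_t <- rep(NA_real_, 4)
  vc <- matrix(NA_real_, 4, 4)
  H <- tryCatch(stats::optimHess(best$par, negll), error = function(e) NULL)
  if (!is.null(H)) {
    vcf <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(vcf) && all(is.finite(vcf)) && all(diag(vcf) > 0)) {
      vc[free, free] <- vcf
      se_t[free] <- sqrt(diag(vcf))
    }
  }
  p_a <- stats::plogis(theta[1])
  p_s <- stats::plogis(theta[2])
  se <- c(p_a = se_t[1] * p_a * (1 - p_a),
          p_s = se_t[2] * p_s * (1 - p_s),
          rho_d = se_t[3], rho_theta = se_t[4])
  structure(list(
    params = bias_params(p_a, p_s, theta[3], theta[4]),
    coefficients = c(p_a = p_a, p_s = p_s, rho_d = theta[3],
                     rho_theta = theta[4], abs_rho_theta = abs(theta[4])),
    se = se,
    theta = theta,
    vcov_theta = vc,
    logLik = -best$value,
    n_choices = attr(tab, "n_steps"),
    n_trials = length(trials),
    converged = best$convergence == 0,
    identifiable = c(p_a = id_pa, p_s = id_ps, rho_d = id_rd,
                     rho_theta = id_rt),
    ref_class = ref_class, s = s, mu_offset = mu_offset),
    class = "bias_fit")
}

#' @export
#' @method print bias_fit
print.bias_fit <- function(x, ...) {
  cat("Sampling-without-replacement choice model (maximum likelihood)\n")
  cat(sprintf("  %d trials, %d choices; logLik = %.2f%s\n",
              x$n_trials, x$n_choices, x$logLik,
              if (x$converged) "" else " (NOT converged)"))
  cat(sprintf("  reference class A: %s; distance scale s = %.1f px\n",
              x$ref_class, x$s))
  print(round(x$coefficients, 4))
  if (!all(x$identifiable))
    cat("  unidentifiable (held at neutrality):",
        paste(names(x$identifiable)[!x$identifiable], collapse = ", "), "\n")
  invisible(x)
}

#' Extract choice-model estimates
#' @param object a [fit_bias()] result.
#' @param ... unused.
#' @return Named vector: `p_a`, `p_s`, `rho_d`, `rho_theta`,
#'   `abs_rho_theta`.
#' @export
coef.bias_fit <- function(object, ...) object$coefficients

#' @export
logLik.bias_fit <- function(object, ...) {
  structure(object$logLik, df = sum(object$identifiable),
            nobs = object$n_choices, class = "logLik")
}

#' Covariance of the transformed parameters
#' @param object a [fit_bias()] result.
#' @param ... unused.
#' @return 4x4 covariance matrix on the `(logit p_a, logit p_s, rho_d,
#'   rho_theta)` scale (`NA` rows for unidentifiable parameters).
#' @export
vcov.bias_fit <- function(object, ...) object$vcov_theta

#' Summarize a choice-model fit
#' @param object a [fit_bias()] result.
#' @param ... unused.
#' @return data.frame of estimates and natural-scale standard errors.
#' @export
#' @method summary bias_fit
summary.bias_fit <- function(object, ...) {
  out <- data.frame(
    estimate = object$coefficients[1:4],
    se = object$se,
    identifiable = object$identifiable)
  attr(out, "logLik") <- object$logLik
  attr(out, "n_choices") <- object$n_choices
  out
}

#' Simulate pick sequences from a fitted choice model
#'
#' @param object a [fit_bias()] result.
#' @param nsim number of sequences.
#' @param seed optional seed (set via `set.seed`).
#' @param display display to forage (required).
#' @param n_picks picks per sequence.
#' @param ... unused.
#' @return List of pick data.frames (see [simulate_sequence()]).
#' @export
simulate.bias_fit <- function(object, nsim = 1, seed = NULL, display,
                              n_picks, ...) {
  if (!is.null(seed)) set.seed(seed)
  replicate(nsim,
            simulate_sequence(display, object$params, n_picks,
                              ref_class = object$ref_class, s = object$s,
                              mu_offset = object$mu_offset),
            simplify = FALSE)
}
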