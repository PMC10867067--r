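#' The ten candidate fixed-effect structures
#'
#' Returns the fixed-effect terms of the ten theoretically plausible models
#' compared for every organization indicator.  All models share the four
#' main effects (log-age, condition, set size, bin); they differ in which
#' interaction products are added:
#'
#' * Model 1: main effects only (k = 7)
#' * Model 2: + age x set size (k = 8)
#' * Model 3: + condition x set size (k = 8)
#' * Model 4: + age x set size + condition x set size (k = 9)
#' * Model 5: + age x bin (k = 8)
#' * Model 6: + bin x condition (k = 8)
#' * Model 7: + age x bin + condition x bin (k = 9)
#' * Model 8: + age x set size + condition x set size + age x bin
#'     + bin x condition (k = 11)
#' * Model 9: Model 8 + age x set size x condition (k = 12)
#' * Model 10: Model 9 + age x set size x condition x bin (k = 13)
#'
#' `k` counts fixed coefficients (including the intercept) plus the
#' random-intercept variance and the residual variance.  The counts above
#' hold under the coding used throughout: `log_age` and `set_size` numeric,
#' `condition` and `bin` binary 0/1, interactions as elementwise products.
#'
#' @param model_id integer 1..10, or `NULL` for the full list.
#' @return A list of character vectors; each element of a vector is one
#'   fixed-effect term, interaction terms written `"a:b"`.
#' @export
candidate_models <- function(model_id = NULL) {
  main <- c("log_age", "condition", "set_size", "bin")
  m <- list(
    main,
    c(main, "log_age:set_size"),
    c(main, "condition:set_size"),
    c(main, "log_age:set_size", "condition:set_size"),
    c(main, "log_age:bin"),
    c(main, "bin:condition"),
    c(main, "log_age:bin", "condition:bin"),
    c(main, "log_age:set_size", "condition:set_size", "log_age:bin",
      "bin:condition"),
    c(main, "log_age:set_size", "condition:set_size", "log_age:bin",
      "bin:condition", "log_age:set_size:condition"),
    c(main, "log_age:set_size", "condition:set_size", "log_age:bin",
      "bin:condition", "log_age:set_size:condition",
      "log_age:set_size:condition:bin"))
  names(m) <- paste0("model", 1:10)
  if (is.null(model_id)) return(m)
  if (!model_id %in% 1:10) stop("unknown model_id: ", model_id)
  m[[model_id]]
}

code_predictors <- function(data) {
  out <- data.frame(
    log_age = as.numeric(data$log_age),
    condition = as.numeric(data$condition == "conjunction"),
    set_size = as.numeric(data$set_size),
    bin = as.numeric(data$bin %in% c("bin2", "2", 2)))
  # accept pre-coded 0/1 columns too
  if (is.numeric(data$condition)) out$condition <- as.numeric(data$condition)
  if (is.numeric(data$bin)) out$bin <- as.numeric(data$bin)
  out
}

#' Build the design matrix for one candidate model
#'
#' Codes the predictors (`log_age` numeric, `set_size` numeric in pixels of
#' items {60, 100, 140, 180}, `condition` 0 = feature / 1 = conjunction,
#' `bin` 0 = first half / 1 = second half), forms the interaction columns as
#' elementwise products, and returns the response, fixed-effect design, and
#' participant grouping vector.
#'
#' @param model_id integer 1..10.
#' @param data data.frame with columns `log_age`, `condition`, `set_size`,
#'   `bin`, `participant`, and the response named by `response`.
#' @param response name of the response column.
#' @return List: `y`, `X` (including the intercept column), `groups`,
#'   `terms`, and `k` (columns of `X` + 2 variance components).
#' @export
build_design <- function(model_id, data, response) {
  terms <- candidate_models(model_id)
  stopifnot(response %in% names(data))
  y <- as.numeric(data[[response]])
  coded <- code_predictors(data)
  cols <- lapply(terms, function(tm) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    Reduce(`*`, coded[parts])
  })
  X <- cbind(`(Intercept)` = 1, do.call(cbind, cols))
  colnames(X) <- c("(Intercept)", terms)
  list(y = y, X = X, groups = as.character(data$participant),
       terms = terms, k = ncol(X) + 2L)
}

#' Fit one candidate linear mixed model by maximum likelihood
#'
#' Fits `y ~ X + (1 | participant)` with `lme4` under full maximum
#' likelihood (not REML): ML is required for AIC comparisons across models
#' with different fixed-effect structures.  A singular fit (random-intercept
#' variance estimated at zero) is retained and flagged, not discarded.
#'
#' @param design a [build_design()] result (or any list with `y`, `X`,
#'   `groups`, `k`).
#' @param model_id identifier carried into the fit record.
#' @return A list of class `"lmm_fit"`: `model_id`, `logLik`, `n`, `k`,
#'   `AIC`, `AICc`, `singular`, `fixef`, and the underlying `lme4` fit.
#' @export
fit_lmm_ml <- function(design, model_id = NA_integer_) {
  y <- design$y
  X <- design$X
  ok <- is.finite(y)
  y <- y[ok]
  X <- X[ok, , drop = FALSE]
  groups <- design$groups[ok]
  n <- length(y)
  k <- ncol(X) + 2L
  if (n <= k + 1L) stop("too few observations (n = ", n, ") for k = ", k)
  if (length(unique(groups)) < 2L) stop("need at least 2 groups")
  df <- data.frame(.y = y, X[, -1L, drop = FALSE], check.names = TRUE)
  xnames <- colnames(df)[-1L]
  df$.g <- groups
  form <- stats::as.formula(paste(
    ".y ~", paste(c("1", xnames), collapse = " + "), "+ (1 | .g)"))
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.nRE = "ignore")
  fit <- lme4::lmer(form, data = df, REML = FALSE, control = ctrl)
  ll <- as.numeric(stats::logLik(fit))
  aic <- -2 * ll + 2 * k
  aicc <- aic + 2 * k * (k + 1) / (n - k - 1)
  structure(list(model_id = model_id, logLik = ll, n = n, k = k,
                 AIC = aic, AICc = aicc,
                 singular = lme4::isSingular(fit),
                 one_obs_per_group = all(table(groups) == 1L),
                 fixef = lme4::fixef(fit), fit = fit),
            class = "lmm_fit")
}

#' @export
#' @method print lmm_fit
print.lmm_fit <- function(x, ...) {
  cat(sprintf(
    "LMM (ML) model %s: n = %d, k = %d, logLik = %.2f, AIC = %.2f, AICc = %.2f%s\n",
    x$model_id, x$n, x$k, x$logLik, x$AIC, x$AICc,
    if (x$singular) " [singular]" else ""))
  invisible(x)
}

#' Fit all ten candidate models to one indicator
#'
#' Drops rows where the response is missing (so all ten models see the
#' identical row set — a requirement for comparable likelihoods) and fits
#' each candidate with [fit_lmm_ml()].
#'
#' @inheritParams build_design
#' @param models which model ids to fit (default all ten).
#' @return Named list of `"lmm_fit"` objects.
#' @export
fit_candidates <- function(data, response, models = 1:10) {
  keep <- is.finite(as.numeric(data[[response]]))
  data <- data[keep, , drop = FALSE]
  fits <- lapply(models, function(id)
    fit_lmm_ml(build_design(id, data, response), model_id = id))
  names(fits) <- paste0("model", models)
  fits
}

#' AIC/AICc comparison table
#'
#' Ranks a candidate set by small-sample-corrected AIC.  `delta` is each
#' model's AICc minus the smallest AICc in the set; the best model has
#' `delta = 0` (ties broken toward the model with fewer parameters).  The
#' table is ordered by model id, not by rank, for side-by-side reading.
#'
#' @param fits list of `"lmm_fit"` objects fitted to the identical rows.
#' @return data.frame: `model_id`, `k`, `n`, `logLik`, `AIC`, `AICc`,
#'   `delta`, `best`, `singular`.
#' @export
aic_table <- function(fits) {
  n <- vapply(fits, function(f) f$n, 0)
  if (length(unique(n)) != 1L)
    stop("fits were computed on differing row counts; ",
         "likelihoods are not comparable")
  tab <- data.frame(
    model_id = vapply(fits, function(f) as.integer(f$model_id), 0L),
    k = vapply(fits, function(f) as.integer(f$k), 0L),
    n = n,
    logLik = vapply(fits, function(f) f$logLik, 0),
    AIC = vapply(fits, function(f) f$AIC, 0),
    AICc = vapply(fits, function(f) f$AICc, 0),
    singular = vapply(fits, function(f) isTRUE(f$singular), NA))
  tab$delta <- tab$AICc - min(tab$AICc)
  is_min <- tab$delta <= 1e-10
  best_row <- which(is_min)[order(tab$k[is_min])][1]
  tab$best <- seq_len(nrow(tab)) == best_row
  tab <- tab[order(tab$model_id),
             c("model_id", "k", "n", "logLik", "AIC", "AICc", "delta",
               "best", "singular")]
  rownames(tab) <- NULL
  tab
}
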