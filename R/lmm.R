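#' Fit the longitudinal mixed model for one response
#'
#' Fits, by maximum likelihood, the Gaussian linear mixed model
#' \deqn{a = \beta_t + \theta_d + u_i + \epsilon,}
#' i.e. categorical fixed effects for time and condition (those named in
#' `fixed`), a random intercept per individual \eqn{u_i \sim N(0, G)}, and
#' i.i.d. Gaussian residuals. ML (not REML) is used throughout because
#' likelihoods of models with different fixed-effect structures are only
#' comparable under ML, which the likelihood-ratio tests require.
#'
#' Fixed factors with a single observed level are dropped with a warning.
#' Designs where every individual is observed once are accepted: the
#' random-intercept variance is then estimated at the boundary (0) and the
#' likelihood coincides with the ordinary least-squares Gaussian
#' likelihood. On non-convergence the optimizer is restarted from up to 3
#' perturbed initializations before the fit is flagged.
#'
#' @param a numeric response vector, one value per design row.
#' @param design data.frame with factors `individual` and the columns named
#'   in `fixed` (typically the `design` element of a [quant_table]).
#' @param fixed character vector of fixed-effect names, a subset of
#'   `c("time", "condition")` (order defines the coefficient order).
#' @return An object of class `lmm_fit`: list with `coefficients` (fixed
#'   effects), `re_variance` (random-intercept variance), `resid_variance`,
#'   `loglik` (ML), `n_params`, `converged`, `fixed` (effects retained) and
#'   `model` (the underlying `lmerMod`).
#' @seealso [lrt_effect]
#' @export
fit_lmm <- function(a, design, fixed = c("time", "condition")) {
  if (length(a) != nrow(design))
    stop("length(a) must equal nrow(design)")
  if (!"individual" %in% names(design))
    stop("design must contain an 'individual' column")
  for (col in intersect(c("individual", "time", "condition"), names(design)))
    design[[col]] <- factor(design[[col]])
  design <- droplevels(design)
  if (nlevels(design$individual) < 2L)
    stop("design must contain at least 2 individuals")
  keep <- vapply(fixed, function(f) {
    ok <- nlevels(factor(design[[f]])) >= 2L
    if (!ok) warning("fixed effect '", f,
                     "' has a single level and was dropped")
    ok
  }, NA)
  fixed <- fixed[keep]
  dat <- design
  dat$.resp <- a
  rhs <- paste(c("1", fixed, "(1 | individual)"), collapse = " + ")
  form <- stats::as.formula(paste(".resp ~", rhs))
  fit <- tryCatch(.fit_ml(form, dat), error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(coefficients = NULL, re_variance = NA_real_,
                          resid_variance = NA_real_, loglik = NA_real_,
                          n_params = NA_integer_, converged = FALSE,
                          fixed = fixed, model = NULL),
                     class = "lmm_fit"))
  }
  conv <- .is_converged(fit)
  tries <- 0L
  while (!conv && tries < 3L) {
    tries <- tries + 1L
    th <- lme4::getME(fit, "theta")
    fit2 <- tryCatch(
      .fit_ml(form, dat, start = abs(th + stats::runif(length(th), 0, 0.5))),
      error = function(e) NULL)
    if (!is.null(fit2) && .is_converged(fit2)) {
      fit <- fit2
      conv <- TRUE
    }
  }
  vc <- lme4::VarCorr(fit)
  ll <- stats::logLik(fit)
  structure(list(coefficients = lme4::fixef(fit),
                 re_variance = as.numeric(vc$individual[1L, 1L]),
                 resid_variance = attr(vc, "sc")^2,
                 loglik = as.numeric(ll),
                 n_params = attr(ll, "df"),
                 converged = conv,
                 fixed = fixed,
                 model = fit),
            class = "lmm_fit")
}

#' @exportS3Method base::print
print.lmm_fit <- function(x, ...) {
  cat("lmm_fit (ML): fixed =", paste(x$fixed, collapse = " + "),
      "| logLik =", format(x$loglik), "| converged =", x$converged, "\n")
  cat("  re_variance =", format(x$re_variance),
      " resid_variance =", format(x$resid_variance), "\n")
  invisible(x)
}

#' Likelihood-ratio test of one fixed effect
#'
#' Compares the full mixed model (all effects in `full`) to the nested
#' model without `dropped`, both fitted by ML. The statistic
#' `2 * (logLik_full - logLik_restricted)` is clipped at 0 (optimizer
#' noise can make it marginally negative for a truly absent effect) and
#' referred to a chi-square distribution with degrees of freedom equal to
#' the number of fixed-effect parameters removed (levels - 1 for a
#' categorical factor).
#'
#' @param a numeric response vector.
#' @param design design data.frame (see [fit_lmm]).
#' @param full character vector of fixed effects in the full model.
#' @param dropped the effect to test; must be an element of `full`.
#' @return An object of class `lrt_result`: list with `stat`, `df`,
#'   `pvalue` (NA when either fit failed to converge) and `effect`.
#' @export
lrt_effect <- function(a, design, full = c("time", "condition"), dropped) {
  if (!dropped %in% full) stop("'dropped' must be an element of 'full'")
  f1 <- fit_lmm(a, design, fixed = full)
  f0 <- fit_lmm(a, design, fixed = setdiff(full, dropped))
  df <- length(f1$coefficients) - length(f0$coefficients)
  if (!isTRUE(f1$converged) || !isTRUE(f0$converged) || df < 1L) {
    return(structure(list(stat = NA_real_, df = df, pvalue = NA_real_,
                          effect = dropped), class = "lrt_result"))
  }
  stat <- max(0, 2 * (f1$loglik - f0$loglik))
  structure(list(stat = stat, df = df,
                 pvalue = stats::pchisq(stat, df, lower.tail = FALSE),
                 effect = dropped),
            class = "lrt_result")
}

#' @exportS3Method base::print
print.lrt_result <- function(x, ...) {
  cat("LRT [", x$effect, "]: stat = ", format(x$stat), ", df = ", x$df,
      ", p = ", format(x$pvalue), "\n", sep = "")
  invisible(x)
}

.lmm_control <- function() {
  lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                    check.nobs.vs.nRE = "ignore",
                    calc.derivs = FALSE,
                    check.conv.singular = "ignore")
}

.fit_ml <- function(form, dat, start = NULL) {
  withCallingHandlers(
    suppressMessages(
      lme4::lmer(form, data = dat, REML = FALSE, start = start,
                 control = .lmm_control())),
    warning = function(w) invokeRestart("muffleWarning"))
}

.is_converged <- function(fit) {
  isTRUE(fit@optinfo$conv$opt == 0) &&
    length(fit@optinfo$conv$lme4$code %||% integer(0)) == 0L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Fast repeated-testing engine: the design (hence the model structure) is
# fixed across the many score columns / metabolites tested in one run, so
# the full and restricted models are built once and updated for each new
# response with lme4::refit(), which is several times faster than a fresh
# lmer() call. `effects` are the fixed effects of the full model;
# restricted templates are built only for `test_effects`. Returns a
# function(a) -> data.frame(effect, stat, df, pvalue).
.lmm_engine <- function(design, effects = c("time", "condition"),
                        test_effects = effects) {
  stopifnot(all(test_effects %in% effects))
  for (col in intersect(c("individual", "time", "condition"), names(design)))
    design[[col]] <- factor(design[[col]])
  design <- droplevels(design)
  usable_model <- effects[vapply(effects,
                                 function(f)
                                   nlevels(factor(design[[f]])) >= 2L,
                                 NA)]
  usable <- intersect(test_effects, usable_model)
  dat <- design
  dat$.resp <- stats::rnorm(nrow(design))
  build <- function(fx) {
    rhs <- paste(c("1", fx, "(1 | individual)"), collapse = " + ")
    .fit_ml(stats::as.formula(paste(".resp ~", rhs)), dat)
  }
  tpl_full <- build(usable_model)
  tpl_restr <- lapply(stats::setNames(usable, usable),
                      function(f) build(setdiff(usable_model, f)))
  dfs <- vapply(usable, function(f) {
    length(lme4::fixef(tpl_full)) - length(lme4::fixef(tpl_restr[[f]]))
  }, 0L)

  refit_ll <- function(tpl, a) {
    fit <- tryCatch(
      withCallingHandlers(
        suppressMessages(lme4::refit(tpl, newresp = a)),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) NULL)
    if (is.null(fit) || !.is_converged(fit)) NA_real_
    else as.numeric(stats::logLik(fit))
  }

  function(a) {
    ll_full <- refit_ll(tpl_full, a)
    res <- lapply(test_effects, function(f) {
      if (!f %in% usable)
        return(data.frame(effect = f, stat = NA_real_, df = NA_integer_,
                          pvalue = NA_real_))
      ll0 <- refit_ll(tpl_restr[[f]], a)
      if (is.na(ll_full) || is.na(ll0))
        return(data.frame(effect = f, stat = NA_real_, df = dfs[[f]],
                          pvalue = NA_real_))
      stat <- max(0, 2 * (ll_full - ll0))
      data.frame(effect = f, stat = stat, df = dfs[[f]],
                 pvalue = stats::pchisq(stat, dfs[[f]], lower.tail = FALSE))
    })
    do.call(rbind, res)
  }
}
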