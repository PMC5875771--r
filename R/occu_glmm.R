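#' Binomial mixed occupancy model
#'
#' Fits a logit-link Bernoulli model of nest-box occupancy with independent
#' Gaussian random intercepts on the grouping levels of the study design:
#' box nested in site (paired-box programmes), site only (single-box
#' programmes), or none, in which case the fit reduces exactly to ordinary
#' logistic regression. Mixed models maximize the Laplace-approximate
#' marginal likelihood (via \pkg{glmmTMB}); the reduction uses
#' [stats::glm()] with a tight IRLS tolerance.
#'
#' @param formula fixed-effects formula, e.g.
#'   `occupied ~ year_std + risk + Field + I(Field^2)`. Backtick
#'   non-syntactic column names (see [occu_formula()]).
#' @param data data frame of box-year rows.
#' @param random random-intercept specification: a one-sided formula
#'   `~ site_id / box_id` (box nested in site) or `~ site_id`, a character
#'   vector of grouping columns ordered outermost first, or `NULL` for no
#'   random effects.
#' @param ... passed to the underlying fitter.
#' @return an object of class `occu_glmm` with components `coefficients`
#'   (term, estimate, se, z, p), `re_sd` (named random-intercept SDs),
#'   `loglik`, `df`, `aic`, `n_obs`, `converged`, `engine` and the
#'   underlying `model`. Wald z is estimate/SE with two-sided normal p.
#' @seealso [wald_table()], [residuals.occu_glmm()], [select_kernel()]
#' @export
occu_glmm <- function(formula, data, random = NULL, ...) {
  groups <- parse_random(random)
  if (is.null(groups)) {
    model <- stats::glm(formula, family = stats::binomial(), data = data,
                        control = stats::glm.control(epsilon = 1e-12, maxit = 100),
                        ...)
    co <- summary(model)$coefficients
    ll <- as.numeric(stats::logLik(model))
    k <- attr(stats::logLik(model), "df")
    conv <- isTRUE(model$converged)
    re_sd <- numeric(0)
    engine <- "glm"
  } else {
    miss <- setdiff(groups, names(data))
    if (length(miss)) stop("grouping column(s) not found: ", paste(miss, collapse = ", "))
    re_term <- paste0("(1 | ", paste(groups, collapse = "/"), ")")
    full <- stats::as.formula(paste(deparse(formula[[2]]), "~",
                                    paste(deparse(formula[[3]]), collapse = " "),
                                    "+", re_term))
    model <- glmmTMB::glmmTMB(full, data = data, family = stats::binomial(), ...)
    co <- summary(model)$coefficients$cond
    ll <- as.numeric(stats::logLik(model))
    k <- attr(stats::logLik(model), "df")
    vc <- glmmTMB::VarCorr(model)$cond
    re_sd <- vapply(vc, function(v) attr(v, "stddev"), numeric(1))
    names(re_sd) <- names(vc)
    conv <- isTRUE(model$fit$convergence == 0) && isTRUE(model$sdr$pdHess) &&
      is.finite(ll)
    engine <- "glmmTMB"
  }
  coefs <- data.frame(term = gsub("`", "", rownames(co)),
                      estimate = co[, 1], se = co[, 2],
                      z = co[, 3], p = co[, 4], row.names = NULL,
                      stringsAsFactors = FALSE)
  if (any(abs(coefs$estimate) > 15))
    warning("possible separation: |coefficient| > 15 for ",
            paste(coefs$term[abs(coefs$estimate) > 15], collapse = ", "))
  structure(list(
    call = match.call(), formula = formula, random = groups,
    coefficients = coefs, re_sd = re_sd,
    loglik = ll, df = k, aic = -2 * ll + 2 * k,
    n_obs = stats::nobs(model), converged = conv,
    engine = engine, model = model
  ), class = "occu_glmm")
}

parse_random <- function(random) {
  if (is.null(random)) return(NULL)
  if (inherits(random, "formula")) {
    term <- random[[length(random)]]
    groups <- all.vars(term)
    if (!length(groups)) stop("empty random-effects formula")
    return(groups)
  }
  if (is.character(random)) {
    if (!length(random)) return(NULL)
    return(random)
  }
  stop("'random' must be NULL, a one-sided formula, or a character vector")
}

#' Build a fixed-effects formula from term names
#'
#' Backticks non-syntactic column names (class labels with spaces,
#' quadratics named `x^2`, interaction products named `a:b`).
#'
#' @param response response column name.
#' @param terms character vector of term (column) names; may be empty, in
#'   which case an intercept-only formula is returned.
#' @return a formula.
#' @export
occu_formula <- function(response, terms) {
  bt <- function(x) ifelse(make.names(x) == x, x, paste0("`", x, "`"))
  rhs <- if (length(terms)) paste(bt(terms), collapse = " + ") else "1"
  stats::as.formula(paste(bt(response), "~", rhs))
}

#' @export
print.occu_glmm <- function(x, ...) {
  cat("binomial occupancy model (", x$engine, ")\n", sep = "")
  cat("  fixed: ", deparse(x$formula), "\n", sep = "")
  if (length(x$random))
    cat("  random intercepts: ", paste(x$random, collapse = " / "), "\n", sep = "")
  cat(sprintf("  n = %d, logLik = %.2f, AIC = %.1f%s\n", x$n_obs, x$loglik,
              x$aic, if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' @export
summary.occu_glmm <- function(object, ...) {
  structure(list(fit = object, table = wald_table(object)),
            class = "summary.occu_glmm")
}

#' @export
print.summary.occu_glmm <- function(x, ...) {
  print(x$fit)
  cat("\nFixed effects (log odds):\n")
  tab <- x$table
  tab$estimate <- sprintf("% .3f", tab$estimate)
  tab$se <- sprintf("%.3f", tab$se)
  tab$z <- sprintf("% .2f", tab$z)
  tab$p <- format.pval(x$table$p, digits = 3, eps = 1e-4)
  print.data.frame(tab, row.names = FALSE)
  if (length(x$fit$re_sd)) {
    cat("\nRandom-intercept SDs:\n")
    print(round(x$fit$re_sd, 4))
  }
  invisible(x)
}

#' Wald coefficient table
#'
#' Per-term estimate, standard error, Wald z (estimate/SE) and two-sided
#' normal p, with significance marked at p < 0.05.
#'
#' @param fit a converged [occu_glmm()] fit.
#' @param alpha significance level for the marker column.
#' @return data frame `term`, `estimate`, `se`, `z`, `p`, `sig`.
#' @export
wald_table <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "occu_glmm"))
  tab <- fit$coefficients
  if (any(tab$se <= 0 | !is.finite(tab$se)))
    stop("degenerate standard error(s) in fit: ",
         paste(tab$term[tab$se <= 0 | !is.finite(tab$se)], collapse = ", "))
  tab$sig <- ifelse(tab$p < alpha, "*", "")
  tab
}

#' @export
coef.occu_glmm <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
vcov.occu_glmm <- function(object, ...) {
  if (object$engine == "glm") stats::vcov(object$model)
  else stats::vcov(object$model)$cond
}

#' @export
logLik.occu_glmm <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$n_obs,
            class = "logLik")
}

#' Fitted occupancy probabilities and linear predictors
#'
#' @param object an [occu_glmm()] fit.
#' @param newdata optional data frame; defaults to the fitting data.
#' @param type `"response"` (probability) or `"link"` (log odds).
#' @param re.form as in \pkg{glmmTMB}: `NULL` (default) conditions on the
#'   random-intercept modes, `NA` gives population-level predictions.
#' @param ... unused.
#' @export
predict.occu_glmm <- function(object, newdata = NULL,
                              type = c("response", "link"),
                              re.form = NULL, ...) {
  type <- match.arg(type)
  if (object$engine == "glm") {
    if (is.null(newdata)) return(stats::predict(object$model, type = type))
    return(stats::predict(object$model, newdata = newdata, type = type))
  }
  if (is.null(newdata))
    stats::predict(object$model, type = type, re.form = re.form)
  else
    stats::predict(object$model, newdata = newdata, type = type,
                   re.form = re.form, allow.new.levels = TRUE)
}

#' Residuals of an occupancy model
#'
#' Pearson residuals `(y - p) / sqrt(p (1 - p))` by default, with deviance
#' and raw response residuals selectable. Fitted probabilities condition on
#' the random-intercept modes; probabilities of exactly 0 or 1 are clipped
#' at 1e-12 with a warning.
#'
#' @param object an [occu_glmm()] fit.
#' @param type residual type.
#' @param ... unused.
#' @export
residuals.occu_glmm <- function(object, type = c("pearson", "deviance", "response"),
                                ...) {
  type <- match.arg(type)
  y <- occu_response(object)
  p <- as.numeric(predict(object, type = "response"))
  if (any(p <= 0 | p >= 1)) {
    warning("fitted probabilities of exactly 0/1 clipped at 1e-12")
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  }
  switch(type,
    pearson = (y - p) / sqrt(p * (1 - p)),
    deviance = sign(y - p) * sqrt(-2 * (y * log(p) + (1 - y) * log(1 - p))),
    response = y - p)
}

occu_response <- function(object) {
  mf <- stats::model.frame(object$model)
  as.numeric(mf[[1]])
}

#' Simulate occupancy outcomes from a fitted model
#'
#' @param object an [occu_glmm()] fit.
#' @param nsim number of simulated response vectors.
#' @param seed optional integer seed.
#' @param ... passed to the underlying `simulate()` method.
#' @return data frame with `nsim` columns of 0/1 outcomes.
#' @export
simulate.occu_glmm <- function(object, nsim = 1, seed = NULL, ...) {
  stats::simulate(object$model, nsim = nsim, seed = seed, ...)
}

#' Effect curve of a single covariate
#'
#' Plots the population-level predicted occupancy probability against one
#' (standardized) covariate, holding all other numeric covariates at 0 and
#' indicators at their reference level.
#'
#' @param x an [occu_glmm()] fit.
#' @param term name of the covariate to vary.
#' @param range range of the covariate (default: observed range).
#' @param n number of curve points.
#' @param quadratic name of a quadratic child column (`"<term>^2"`) to move
#'   together with the parent, if present in the model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.occu_glmm <- function(x, term, range = NULL, n = 101,
                           quadratic = paste0(term, "^2"), ...) {
  tab <- x$coefficients
  if (!term %in% tab$term) stop("term '", term, "' is not in the model")
  mf <- stats::model.frame(x$model)
  if (is.null(range)) {
    obs <- mf[[term]]
    if (is.null(obs)) obs <- c(-2, 2)
    range <- base::range(obs)
  }
  grid <- seq(range[1], range[2], length.out = n)
  beta <- stats::setNames(tab$estimate, tab$term)
  eta <- beta[["(Intercept)"]] + beta[[term]] * grid
  if (quadratic %in% tab$term) eta <- eta + beta[[quadratic]] * grid^2
  p <- stats::plogis(eta)
  graphics::plot(grid, p, type = "l", xlab = term,
                 ylab = "occupancy probability", ylim = c(0, max(p) * 1.05), ...)
  invisible(data.frame(term = grid, probability = p))
}
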