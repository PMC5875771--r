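sim_glm_data <- function(seed, n = 400, k = 3) {
  set.seed(seed)
  X <- cbind(1, matrix(rnorm(n * k), n, k))
  beta <- c(-0.5, runif(k, -1, 1))
  y <- rbinom(n, 1, plogis(X %*% beta))
  list(X = X, y = y,
       df = data.frame(y = y, X[, -1, drop = FALSE] |>
                         `colnames<-`(paste0("x", seq_len(k)))))
}

test_that("the random-effect-free fit matches an independent IRLS oracle", {
  for (seed in c(2, 13, 27)) {
    d <- sim_glm_data(seed)
    fit <- occu_glmm(y ~ x1 + x2 + x3, data = d$df, random = NULL)
    oracle <- irls_logistic(d$X, d$y)
    expect_equal(unname(coef(fit)), oracle$coefficients, tolerance = 1e-6)
    expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-6)
    expect_equal(fit$df, 4)
    expect_equal(fit$aic, -2 * fit$loglik + 2 * 4)
    expect_true(fit$converged)
  }
})

test_that("AIC identity holds and counts variance parameters in mixed fits", {
  sim <- small_flying_sim(21, n_sites = 60, years = 2002:2007)
  d <- recovery_design(sim)
  fit <- occu_glmm(recovery_formula(), d, random = ~ site_id / box_id)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$df)
  expect_equal(fit$df, 5 + 2)  # five fixed terms, two variance parameters
  expect_length(fit$re_sd, 2)
  expect_equal(fit$n_obs, nrow(d))
  # character shorthand and formula shorthand agree
  fit2 <- occu_glmm(recovery_formula(), d, random = c("site_id", "box_id"))
  expect_equal(coef(fit), coef(fit2))
})

test_that("mixed estimates agree with lme4::glmer on the same data", {
  sim <- small_flying_sim(22, n_sites = 50, years = 2002:2007)
  d <- recovery_design(sim)
  fit <- occu_glmm(recovery_formula(), d, random = ~ site_id / box_id)
  g <- lme4::glmer(
    occupied ~ year_std + risk_std + Field_std + `Field_std^2` +
      (1 | site_id / box_id),
    data = d, family = binomial)
  expect_equal(unname(coef(fit)), unname(lme4::fixef(g)), tolerance = 0.02)
  expect_equal(fit$loglik, as.numeric(logLik(g)), tolerance = 0.05)
})

test_that("Wald statistics follow z = estimate/SE with two-sided normal p", {
  d <- sim_glm_data(5)
  fit <- occu_glmm(y ~ x1 + x2 + x3, data = d$df, random = NULL)
  tab <- wald_table(fit)
  expect_equal(tab$z, tab$estimate / tab$se)
  expect_equal(tab$p, 2 * pnorm(-abs(tab$z)))
  expect_equal(tab$sig, ifelse(tab$p < 0.05, "*", ""))
  # the headline magnitude: estimate -2.41, SE 0.45 gives |z| ~ 5.36
  expect_equal(-2.41 / 0.45, -5.356, tolerance = 1e-3)
  broken <- fit
  broken$coefficients$se[2] <- 0
  expect_error(wald_table(broken), "degenerate")
})

test_that("Wald p-values are invariant to affine covariate rescaling", {
  d <- sim_glm_data(8)$df
  f1 <- occu_glmm(y ~ x1 + x2 + x3, data = d, random = NULL)
  d2 <- d
  d2$x1 <- 100 * d2$x1 + 7
  f2 <- occu_glmm(y ~ x1 + x2 + x3, data = d2, random = NULL)
  t1 <- wald_table(f1)
  t2 <- wald_table(f2)
  expect_equal(t1$p[t1$term != "(Intercept)"],
               t2$p[t2$term != "(Intercept)"], tolerance = 1e-6)
  expect_equal(t2$estimate[t2$term == "x1"] * 100,
               t1$estimate[t1$term == "x1"], tolerance = 1e-6)
})

test_that("destandardizing fitted slopes reproduces the raw-covariate fit", {
  set.seed(14)
  n <- 500
  raw <- data.frame(x = rnorm(n, 50, 9), w = rnorm(n, -3, 0.5))
  raw$y <- rbinom(n, 1, plogis(-1 + 0.05 * raw$x + 0.8 * raw$w))
  fr <- occu_glmm(y ~ x + w, data = raw, random = NULL)
  std <- raw
  sx <- standardize(std$x); sw <- standardize(std$w)
  std$x <- as.numeric(sx); std$w <- as.numeric(sw)
  fs <- occu_glmm(y ~ x + w, data = std, random = NULL)
  b <- coef(fs)
  back <- c(b[1] - b[2] * attr(sx, "center") / attr(sx, "scale") -
              b[3] * attr(sw, "center") / attr(sw, "scale"),
            b[2] / attr(sx, "scale"), b[3] / attr(sw, "scale"))
  expect_equal(unname(back), unname(coef(fr)), tolerance = 1e-6)
})

test_that("fit methods expose residuals, predictions and simulations coherently", {
  set.seed(6)
  d <- data.frame(y = rep(c(0, 1), each = 20))
  fit <- occu_glmm(y ~ 1, data = d, random = NULL)
  # intercept-only balanced fit: p-hat = 1/2, Pearson residuals are +-1
  expect_equal(unname(residuals(fit, "pearson")), rep(c(-1, 1), each = 20))
  expect_equal(unname(residuals(fit, "response")), rep(c(-0.5, 0.5), each = 20))
  sim <- small_flying_sim(23, n_sites = 40, years = 2002:2005)
  dd <- recovery_design(sim)
  mfit <- occu_glmm(recovery_formula(), dd, random = ~ site_id / box_id)
  r <- residuals(mfit)
  p <- predict(mfit, type = "response")
  expect_length(r, nrow(dd))
  expect_true(all(p > 0 & p < 1))
  expect_equal(r, (dd$occupied - p) / sqrt(p * (1 - p)), tolerance = 1e-10)
  ysim <- simulate(mfit, nsim = 2, seed = 1)
  expect_equal(dim(ysim), c(nrow(dd), 2))
  expect_true(all(unlist(ysim) %in% 0:1))
  grDevices::pdf(NULL)
  curve <- plot(mfit, "risk_std")
  grDevices::dev.off()
  expect_true(all(curve$probability >= 0 & curve$probability <= 1))
})
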