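test_that("flat-top Gaussian kernel has the analytic plateau/flank/cutoff shape", {
  p <- kernel_params(sd_m = 2000, flat_top_m = 1000)
  expect_equal(kernel_height(0, p), 1)
  expect_equal(kernel_height(1000, p), 1)
  expect_equal(kernel_height(1000 + 2000, p), exp(-1 / 2))
  expect_equal(kernel_height(10001, p), 0)
  expect_error(kernel_height(-1, p), "non-negative")
  # continuity at the plateau edge, and the only jump is at the cut-off
  eps <- 1e-9
  expect_equal(kernel_height(1000 + eps, p), 1, tolerance = 1e-12)
  jump <- kernel_height(10000, p) - kernel_height(10000 + eps, p)
  expect_equal(jump, exp(-(10000 - 1000)^2 / (2 * 2000^2)))
  expect_error(kernel_params(0, 500), "sd_m")
  expect_error(kernel_params(1000, -1), "flat_top_m")
  expect_error(kernel_params(1000, 2000, 1500), "cutoff")
})

test_that("kernel height is non-increasing in distance", {
  for (p in list(kernel_params(1000, 500), kernel_params(3000, 2500),
                 kernel_params(4000, 500))) {
    h <- kernel_height(seq(0, 10000, by = 10), p)
    expect_true(all(diff(h) <= 1e-15))
    expect_true(all(h >= 0 & h <= 1))
  }
})

test_that("risk at a point aggregates nests by sum or pointwise maximum", {
  p <- kernel_params(2000, 1000)
  one <- data.frame(x = 1000, y = 0)
  expect_equal(risk_at_point(0, 0, one, p, "sum"), 1)
  expect_equal(risk_at_point(0, 0, one, p, "max"), 1)
  two <- data.frame(x = c(500, 500), y = c(0, 0))
  expect_equal(risk_at_point(0, 0, two, p, "sum"), 2)
  expect_equal(risk_at_point(0, 0, two, p, "max"), 1)
  expect_equal(risk_at_point(0, 0, two[0, ], p), 0)
  mixed <- data.frame(x = c(0, 1), y = c(0, 0), year = c(2002, 2003))
  expect_error(risk_at_point(0, 0, mixed, p), "year")
  # hand-summed three-nest oracle
  d <- c(800, 2500, 6000)
  nests <- data.frame(x = d, y = 0)
  expect_equal(risk_at_point(0, 0, nests, p, "sum"),
               1 + exp(-(2500 - 1000)^2 / (2 * 2000^2)) +
                 exp(-(6000 - 1000)^2 / (2 * 2000^2)))
})

test_that("sum-aggregation is additive over disjoint nest subsets, max is the join", {
  set.seed(5)
  p <- kernel_params(2500, 500)
  nests <- data.frame(x = runif(12, -8000, 8000), y = runif(12, -8000, 8000))
  a <- nests[1:5, ]
  b <- nests[6:12, ]
  expect_equal(risk_at_point(0, 0, nests, p, "sum"),
               risk_at_point(0, 0, a, p, "sum") + risk_at_point(0, 0, b, p, "sum"))
  expect_equal(risk_at_point(0, 0, nests, p, "max"),
               max(risk_at_point(0, 0, a, p, "max"),
                   risk_at_point(0, 0, b, p, "max")))
})

test_that("risk covariates honour the lag and fill missing predator years", {
  boxes <- data.frame(box_id = c("b1", "b2"), x = c(0, 20000), y = 0)
  nests <- data.frame(species = "ural_owl", year = c(2002, 2003), x = 500, y = 0)
  p <- kernel_params(2000, 1000)
  # lag 1 for 2002 needs 2001, absent: filled from the nearest (later) year
  expect_message(
    rc <- risk_covariate(boxes, nests, p, years = 2002:2003, lag = 1),
    "2001")
  r02 <- rc[rc$year == 2002 & rc$box_id == "b1", ]
  expect_true(r02$filled)
  expect_equal(r02$source_year, 2002)
  expect_equal(r02$value, 1)
  expect_false(rc$filled[rc$year == 2003][1])
  # a box beyond the cut-off from every nest scores zero everywhere
  expect_true(all(rc$value[rc$box_id == "b2"] == 0))
  expect_error(
    risk_covariate(boxes, nests, p, years = 2002:2003, lag = 1, fill = FALSE),
    "2001")
  # static nests make lag irrelevant
  static <- data.frame(species = "ural_owl", year = 2001:2003, x = 500, y = 0)
  r0 <- risk_covariate(boxes, static, p, years = 2002:2003, lag = 0)
  r1 <- risk_covariate(boxes, static, p, years = 2002:2003, lag = 1)
  expect_equal(r0$value, r1$value)
})

test_that("kernel covariate scale is absorbed by standardization", {
  # multiplying every kernel height by c > 0 leaves all slopes unchanged
  set.seed(31)
  n <- 400
  risk <- rexp(n)
  x2 <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 - 0.8 * scale(risk)[, 1] + 0.5 * x2))
  d1 <- data.frame(y = y, r = as.numeric(standardize(risk)), x2 = x2)
  d2 <- data.frame(y = y, r = as.numeric(standardize(risk * 7.3)), x2 = x2)
  f1 <- occu_glmm(y ~ r + x2, d1)
  f2 <- occu_glmm(y ~ r + x2, d2)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
})

test_that("AIC ties in the kernel grid search break toward the smaller plateau", {
  # geometry making two candidates produce identical covariates: boxes are
  # either on both plateaus or beyond both cut-offs
  set.seed(9)
  boxes <- data.frame(box_id = sprintf("b%02d", 1:40),
                      x = c(runif(20, -300, 300), runif(20, 30000, 40000)),
                      y = runif(40, -300, 300))
  nests <- data.frame(species = "ural_owl", year = 2001:2003, x = 0, y = 0)
  occ <- expand.grid(box_id = boxes$box_id, year = 2002:2003,
                     stringsAsFactors = FALSE)
  occ$occupied <- rbinom(nrow(occ), 1, 0.4)
  sel <- select_kernel(occ, boxes, nests, formula = occupied ~ 1,
                       random = NULL, sd_m = 3000,
                       flat_top_m = c(1000, 500), lags = 1)
  expect_equal(sel$best$flat_top_m, 500)
  expect_equal(sel$delta_aic, 0)
  expect_equal(nrow(sel$table), 2)
})
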