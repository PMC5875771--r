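# Independent oracles used across the suite. Each is a deliberately naive
# implementation (loops, Newton iterations written out) kept separate from
# the package code paths it checks.

# Newton-Raphson logistic regression (IRLS oracle)
irls_logistic <- function(X, y, tol = 1e-12, maxit = 100) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    grad <- crossprod(X, y - p)
    H <- crossprod(X * W, X)
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- as.numeric(X %*% beta)
  p <- 1 / (1 + exp(-eta))
  list(coefficients = as.numeric(beta),
       loglik = sum(y * log(p) + (1 - y) * log(1 - p)),
       iterations = it)
}

# brute-force cell-centre buffer composition (loop over every cell)
brute_composition <- function(grid, x, y, radius_m) {
  counts <- list()
  for (row in seq_len(grid$n_rows)) {
    for (col in seq_len(grid$n_cols)) {
      code <- grid$cells[row, col]
      if (code == grid$nodata_code) next
      cx <- grid$origin_x + (col - 0.5) * grid$cell_size
      cy <- grid$origin_y + (grid$n_rows - row + 0.5) * grid$cell_size
      if ((cx - x)^2 + (cy - y)^2 <= radius_m^2) {
        key <- as.character(code)
        counts[[key]] <- (counts[[key]] %||% 0) + 1
      }
    }
  }
  cell_ha <- grid$cell_size^2 / 1e4
  out <- vapply(counts, function(n) n * cell_ha, numeric(1))
  out[order(as.integer(names(out)))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force Moran's I: explicit double sum over ordered pairs
brute_moran <- function(values, coords, radius_m) {
  n0 <- length(values)
  keep <- logical(n0)
  w <- matrix(0, n0, n0)
  for (i in seq_len(n0)) {
    for (j in seq_len(n0)) {
      if (i == j) next
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      if (d <= radius_m) w[i, j] <- 1
    }
  }
  keep <- rowSums(w) > 0
  w <- w[keep, keep, drop = FALSE]
  x <- values[keep]
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + w[i, j] * z[i] * z[j]
  (n / sum(w)) * num / sum(z^2)
}

# uniform single-class test grid
uniform_grid <- function(n = 40, cell = 25, code = 11L) {
  land_grid(matrix(code, n, n), 0, 0, cell)
}

# small flying-squirrel simulation used by several model tests; coarse
# class mix keeps rare-class separation out of small fixtures
coarse_mix <- function() {
  c("Clear cut" = 0.12, "Y pine" = 0.12, "Y mix" = 0.18,
    "Mo pine" = 0.18, "Mo spruce" = 0.20, "Bog" = 0.08, "Field" = 0.12)
}

small_flying_sim <- function(seed, n_sites = 50, years = 2002:2007, ...) {
  simulate_study(sim_config("flying", seed = seed, n_sites = n_sites,
                            years = years, margin_m = 300,
                            class_mix = coarse_mix(), ...))
}

# standardized truth-term design for refitting simulated data
recovery_design <- function(sim) {
  d <- sim$occ
  d$risk_std <- as.numeric(standardize(d$risk))
  d$Field_std <- as.numeric(standardize(d$Field))
  d$year_std <- as.numeric(standardize(d$year))
  d <- add_quadratic(d, "Field_std")
  d
}

recovery_formula <- function() {
  occu_formula("occupied", c("year_std", "risk_std", "Field_std", "Field_std^2"))
}
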