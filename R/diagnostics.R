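#' Moran's I with distance-band weights
#'
#' Spatial autocorrelation of a set of values at point locations, using
#' binary (non-row-standardized) weights `w_ij = 1` iff
#' `0 < d(i, j) <= radius_m`. Values sharing an identical coordinate are
#' averaged first (box-level residuals at a shared site location). Units
#' with no neighbour inside the radius carry no information under this
#' weight matrix and are dropped before the statistic is computed; `n`
#' reports the units retained. Inference uses the normal approximation by
#' default, with an optional permutation test.
#'
#' @param values numeric vector (e.g. model residuals).
#' @param coords two-column matrix or data frame of x/y coordinates (m).
#' @param radius_m neighbourhood radius in metres.
#' @param nperm if > 0, also run a permutation test with this many
#'   permutations (seed the RNG beforehand for reproducibility).
#' @return object of class `moran_result`: a list with `radius_m`, `n`, `I`,
#'   `expected` (`-1/(n-1)`), `variance`, `z`, `p` (two-sided normal), `W`
#'   (sum of weights) and, when requested, `p_perm`.
#' @export
morans_i <- function(values, coords, radius_m, nperm = 0) {
  coords <- as.matrix(coords)
  if (nrow(coords) != length(values)) stop("values and coords differ in length")
  key <- paste(coords[, 1], coords[, 2])
  if (anyDuplicated(key)) {
    uk <- unique(key)
    values <- vapply(uk, function(k) mean(values[key == k]), numeric(1))
    coords <- coords[match(uk, key), , drop = FALSE]
  }
  n0 <- length(values)
  if (n0 < 3L) stop("need at least 3 distinct locations")
  d <- as.matrix(stats::dist(coords))
  w <- (d > 0 & d <= radius_m) * 1
  keep <- rowSums(w) > 0
  if (!any(keep)) stop("empty weight matrix: no pair of units within ",
                       radius_m, " m")
  w <- w[keep, keep, drop = FALSE]
  x <- values[keep]
  n <- length(x)
  if (n < 3L) stop("fewer than 3 units have neighbours within ", radius_m, " m")
  if (stats::var(x) == 0) stop("constant values: Moran's I is undefined")
  z <- x - mean(x)
  W <- sum(w)
  I <- (n / W) * sum(w * outer(z, z)) / sum(z^2)
  EI <- -1 / (n - 1)
  S1 <- 2 * W          # binary symmetric weights: 0.5 * sum((w + t(w))^2)
  S2 <- sum((2 * rowSums(w))^2)
  varI <- (n^2 * S1 - n * S2 + 3 * W^2) / (W^2 * (n^2 - 1)) - EI^2
  zstat <- (I - EI) / sqrt(varI)
  res <- structure(list(radius_m = radius_m, n = n, I = I, expected = EI,
                        variance = varI, z = zstat,
                        p = 2 * stats::pnorm(-abs(zstat)), W = W),
                   class = "moran_result")
  if (nperm > 0) {
    perm <- vapply(seq_len(nperm), function(i) {
      zz <- sample(z)
      (n / W) * sum(w * outer(zz, zz)) / sum(zz^2)
    }, numeric(1))
    res$p_perm <- (1 + sum(abs(perm - EI) >= abs(I - EI))) / (nperm + 1)
  }
  res
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I at %g m: I = %.4f (expected %.4f), z = %.3f, p = %.4g, n = %d\n",
              x$radius_m, x$I, x$expected, x$z, x$p, x$n))
  if (!is.null(x$p_perm)) cat(sprintf("  permutation p = %.4g\n", x$p_perm))
  invisible(x)
}

#' Spatial autocorrelation diagnostics for an occupancy model
#'
#' Pearson residuals of the fit are averaged per box across years (the
#' default; set `per_year = FALSE` off to test each year separately) and
#' Moran's I is computed at each radius. Radii at which the weight matrix is
#' empty (e.g. 50 m in a design whose closest boxes are 80--100 m apart) are
#' reported with an `error` note rather than a statistic.
#'
#' @param fit an [occu_glmm()] fit.
#' @param data the box-year data used to fit, holding `box_id`, `x`, `y`.
#' @param radii neighbourhood radii in metres.
#' @param per_year compute per-box means across years first (default TRUE)?
#' @return data frame `radius_m`, `n`, `I`, `expected`, `variance`, `z`,
#'   `p`, `note` (with `year` when `per_year = FALSE`).
#' @export
moran_diagnostics <- function(fit, data, radii = c(50, 500, 5000),
                              per_year = TRUE) {
  stopifnot(all(c("box_id", "x", "y") %in% names(data)))
  r <- residuals(fit, type = "pearson")
  if (length(r) != nrow(data))
    stop("residual length does not match 'data' rows")
  run <- function(vals, xy, radius, year = NA) {
    out <- tryCatch({
      m <- morans_i(vals, xy, radius)
      data.frame(year = year, radius_m = radius, n = m$n, I = m$I,
                 expected = m$expected, variance = m$variance, z = m$z,
                 p = m$p, note = "", stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(year = year, radius_m = radius, n = NA_integer_, I = NA_real_,
                 expected = NA_real_, variance = NA_real_, z = NA_real_,
                 p = NA_real_, note = conditionMessage(e), stringsAsFactors = FALSE))
    out
  }
  if (per_year) {
    agg <- stats::aggregate(r, by = list(box_id = data$box_id), FUN = mean)
    xy <- data[match(agg$box_id, data$box_id), c("x", "y")]
    res <- do.call(rbind, lapply(radii, function(rad) run(agg$x, xy, rad)))
    res$year <- NULL
  } else {
    res <- do.call(rbind, lapply(sort(unique(data$year)), function(yr) {
      sel <- data$year == yr
      do.call(rbind, lapply(radii, function(rad)
        run(r[sel], data[sel, c("x", "y")], rad, year = yr)))
    }))
  }
  rownames(res) <- NULL
  res
}
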