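#' Flat-top Gaussian kernel parameters
#'
#' The predation-risk surface around a predator nest is flat (height 1) out
#' to a plateau radius, declines as a Gaussian with standard deviation
#' `sd_m` beyond it, and is truncated to 0 past a cut-off distance.
#'
#' @param sd_m Gaussian SD of the decaying flank, metres (> 0).
#' @param flat_top_m plateau radius, metres (>= 0).
#' @param cutoff_m truncation distance, metres (default 10000).
#' @return an object of class `kernel_params`.
#' @export
kernel_params <- function(sd_m, flat_top_m, cutoff_m = 10000) {
  if (!is.numeric(sd_m) || sd_m <= 0) stop("'sd_m' must be > 0")
  if (!is.numeric(flat_top_m) || flat_top_m < 0) stop("'flat_top_m' must be >= 0")
  if (!is.numeric(cutoff_m) || cutoff_m <= flat_top_m)
    stop("'cutoff_m' must exceed 'flat_top_m'")
  structure(list(sd_m = as.numeric(sd_m), flat_top_m = as.numeric(flat_top_m),
                 cutoff_m = as.numeric(cutoff_m)), class = "kernel_params")
}

#' @export
print.kernel_params <- function(x, ...) {
  cat(sprintf("flat-top Gaussian kernel: plateau %g m, SD %g m, cut-off %g m\n",
              x$flat_top_m, x$sd_m, x$cutoff_m))
  invisible(x)
}

#' Height of the flat-top Gaussian kernel
#'
#' Height 1 on the plateau (`d <= flat_top_m`), then
#' `exp(-(d - flat_top_m)^2 / (2 sd_m^2))` out to the cut-off, 0 beyond.
#' Continuous at the plateau edge; the only discontinuity is the truncation
#' jump at the cut-off.
#'
#' @param distance_m vector of distances in metres (>= 0).
#' @param params a [kernel_params()].
#' @return heights in `[0, 1]`.
#' @export
kernel_height <- function(distance_m, params) {
  stopifnot(inherits(params, "kernel_params"))
  if (any(distance_m < 0)) stop("'distance_m' must be non-negative")
  h <- ifelse(distance_m <= params$flat_top_m, 1,
              exp(-(distance_m - params$flat_top_m)^2 / (2 * params$sd_m^2)))
  h[distance_m > params$cutoff_m] <- 0
  h
}

#' Predation-risk value at a point
#'
#' Aggregates kernel heights over the nests of one predator species in one
#' year: `"sum"` adds the per-nest heights (cumulative exposure from
#' multiple territories), `"max"` takes the pointwise maximum.
#'
#' @param x,y point coordinates in metres.
#' @param nests data frame with columns `x`, `y` (and optionally `species`,
#'   `year`, which must then be constant).
#' @param params a [kernel_params()].
#' @param aggregation `"sum"` (default) or `"max"`.
#' @return a non-negative risk value (0 for an empty nest set).
#' @export
risk_at_point <- function(x, y, nests, params, aggregation = c("sum", "max")) {
  aggregation <- match.arg(aggregation)
  if (NROW(nests) == 0L) return(0)
  for (col in c("species", "year"))
    if (col %in% names(nests) && length(unique(nests[[col]])) > 1L)
      stop("nest set mixes multiple values of '", col, "'")
  d <- sqrt((nests$x - x)^2 + (nests$y - y)^2)
  h <- kernel_height(d, params)
  if (aggregation == "sum") sum(h) else max(h)
}

#' Kernel risk covariate for nest boxes across years
#'
#' For each box and analysis year, the aggregated kernel height over one
#' predator species' nests from year `year - lag`. A predator year missing
#' from the nest table is filled from the nearest available year (ties
#' broken toward the later year, matching the practice of carrying a later
#' census backwards), flagged in the output and reported via `message()`;
#' with `fill = FALSE` a missing year is an error.
#'
#' @param boxes data frame with `box_id`, `x`, `y`.
#' @param nests data frame with `species`, `year`, `x`, `y` for one species.
#' @param params a [kernel_params()].
#' @param years analysis years to cover.
#' @param lag 0 (current-year nests) or 1 (previous-year nests).
#' @param aggregation `"sum"` or `"max"`, see [risk_at_point()].
#' @param fill fill missing predator years from the nearest available year?
#' @return data frame `box_id`, `year`, `value`, `lag`, `source_year`,
#'   `filled`.
#' @export
risk_covariate <- function(boxes, nests, params, years, lag = 1,
                           aggregation = c("sum", "max"), fill = TRUE) {
  aggregation <- match.arg(aggregation)
  if (!lag %in% c(0, 1)) stop("'lag' must be 0 or 1")
  if (length(unique(nests$species)) > 1L)
    stop("nest table mixes species; filter to one predator first")
  avail <- sort(unique(nests$year))
  if (!length(avail)) stop("nest table is empty")
  out <- vector("list", length(years))
  for (k in seq_along(years)) {
    yr <- years[k]
    want <- yr - lag
    src <- want
    filled <- FALSE
    if (!want %in% avail) {
      if (!fill)
        stop("no predator nest data for required year ", want,
             " (available: ", paste(avail, collapse = ", "), ")")
      gap <- abs(avail - want)
      cand <- avail[gap == min(gap)]
      src <- max(cand)  # prefer the later year on ties
      filled <- TRUE
      message("risk_covariate: predator year ", want,
              " missing; using nests from ", src)
    }
    ny <- nests[nests$year == src, , drop = FALSE]
    if (nrow(ny)) {
      dx <- outer(boxes$x, ny$x, "-")
      dy <- outer(boxes$y, ny$y, "-")
      h <- kernel_height(sqrt(dx * dx + dy * dy), params)
      h <- matrix(h, nrow = nrow(boxes))
      val <- if (aggregation == "sum") rowSums(h) else apply(h, 1L, max)
    } else val <- numeric(nrow(boxes))
    out[[k]] <- data.frame(box_id = boxes$box_id, year = yr, value = val,
                           lag = lag, source_year = src, filled = filled,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' AIC grid search over kernel hyperparameters and temporal lag
#'
#' Refits the full occupancy model once per candidate combination of kernel
#' SD, plateau radius and lag, and selects the most parsimonious candidate
#' by model AIC. The candidate risk covariate is standardized before entering
#' the model. Non-converged fits (and candidates whose risk covariate is
#' constant) are recorded but excluded from the arg-min. Ties are broken
#' toward the smaller plateau, then the smaller SD, then lag 1.
#'
#' @param occ box-year data frame holding the response and all non-risk
#'   covariate columns, plus `box_id` and `year` for joining the candidate
#'   risk column.
#' @param boxes nest-box table (`box_id`, `x`, `y`).
#' @param nests predator nest table for one species.
#' @param formula fixed-effects formula of the full model *without* the risk
#'   term, e.g. `occupied ~ year_std + Field + I(Field^2)`.
#' @param random random-intercept specification passed to [occu_glmm()].
#' @param sd_m,flat_top_m candidate vectors in metres (defaults: the
#'   1--4 km SD by 500--2500 m plateau grid).
#' @param lags candidate lags (default both 0 and 1).
#' @param cutoff_m kernel truncation distance.
#' @param aggregation passed to [risk_covariate()].
#' @param risk_name name for the standardized risk column added to the model.
#' @param quadratic also include the squared risk term (used for the goshawk
#'   term in flying-squirrel models)?
#' @param ... further arguments to [occu_glmm()].
#' @return an object of class `kernel_selection`: the full AIC table
#'   (`$table`), the selected [kernel_params()] (`$best`), `$best_lag`, and
#'   `$delta_aic` to the runner-up.
#' @export
select_kernel <- function(occ, boxes, nests, formula, random,
                          sd_m = c(1000, 2000, 3000, 4000),
                          flat_top_m = c(500, 1000, 1500, 2000, 2500),
                          lags = c(0, 1), cutoff_m = 10000,
                          aggregation = c("sum", "max"),
                          risk_name = "risk", quadratic = FALSE, ...) {
  aggregation <- match.arg(aggregation)
  if (!length(sd_m) || !length(flat_top_m) || !length(lags))
    stop("candidate lists must be non-empty")
  years <- sort(unique(occ$year))
  grid <- expand.grid(sd_m = sd_m, flat_top_m = flat_top_m, lag = lags,
                      KEEP.OUT.ATTRS = FALSE)
  grid$AIC <- NA_real_
  grid$logLik <- NA_real_
  grid$converged <- FALSE
  rhs <- paste(deparse(formula[[3]]), collapse = " ")
  resp <- deparse(formula[[2]])
  add <- risk_name
  if (quadratic) add <- c(add, sprintf("I(%s^2)", risk_name))
  full_formula <- stats::as.formula(
    paste(resp, "~", rhs, "+", paste(add, collapse = " + ")))
  for (i in seq_len(nrow(grid))) {
    params <- kernel_params(grid$sd_m[i], grid$flat_top_m[i], cutoff_m)
    rc <- suppressMessages(
      risk_covariate(boxes, nests, params, years, lag = grid$lag[i],
                     aggregation = aggregation))
    d <- occ
    d[[risk_name]] <- rc$value[match(paste(d$box_id, d$year),
                                     paste(rc$box_id, rc$year))]
    fit <- tryCatch({
      if (stats::sd(d[[risk_name]]) == 0)
        stop("constant risk covariate for this candidate")
      d[[risk_name]] <- standardize(d[[risk_name]], name = risk_name)
      occu_glmm(full_formula, data = d, random = random, ...)
    }, error = function(e) NULL)
    if (!is.null(fit)) {
      grid$AIC[i] <- fit$aic
      grid$logLik[i] <- fit$loglik
      grid$converged[i] <- fit$converged
    }
  }
  ok <- which(grid$converged)
  if (!length(ok)) stop("kernel selection failed: no candidate model converged")
  ord <- ok[order(grid$AIC[ok], grid$flat_top_m[ok], grid$sd_m[ok], -grid$lag[ok])]
  best <- ord[1]
  delta <- if (length(ord) > 1L) grid$AIC[ord[2]] - grid$AIC[best] else NA_real_
  structure(list(
    table = grid,
    best = kernel_params(grid$sd_m[best], grid$flat_top_m[best], cutoff_m),
    best_lag = grid$lag[best],
    delta_aic = delta,
    aggregation = aggregation
  ), class = "kernel_selection")
}

#' @export
print.kernel_selection <- function(x, ...) {
  cat("kernel selection over", nrow(x$table), "candidates\n")
  cat(sprintf("  selected: SD %g m, flat top %g m, lag %d (delta AIC to runner-up %.2f)\n",
              x$best$sd_m, x$best$flat_top_m, x$best_lag, x$delta_aic))
  invisible(x)
}
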