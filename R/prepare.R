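#' First-visit cleaning of nest-box census data
#'
#' Reduces a raw visit table to one presence/absence record per box and
#' year: only the earliest visit of each box-year counts (equal search
#' effort across boxes), and box-years whose first visit falls after the
#' census cut-off month are dropped.
#'
#' @param visits data frame with columns `box_id`, `date` (Date or
#'   "YYYY-MM-DD" text) and `occupied` (0/1).
#' @param last_month last admissible month of the first visit (default 6,
#'   i.e. checked by the end of June).
#' @return data frame `box_id`, `year`, `occupied`, one row per box-year.
#' @export
first_visit_filter <- function(visits, last_month = 6) {
  stopifnot(all(c("box_id", "date", "occupied") %in% names(visits)))
  d <- if (inherits(visits$date, "Date")) visits$date
  else as.Date(as.character(visits$date), format = "%Y-%m-%d")
  bad <- which(is.na(d) & !is.na(visits$date))
  if (length(bad))
    stop("unparseable date(s) at row(s) ", paste(utils::head(bad, 5), collapse = ", "))
  if (anyNA(d)) stop("missing date(s) at row(s) ",
                     paste(utils::head(which(is.na(d)), 5), collapse = ", "))
  v <- data.frame(box_id = visits$box_id, date = d,
                  year = as.integer(format(d, "%Y")),
                  month = as.integer(format(d, "%m")),
                  occupied = as.integer(visits$occupied),
                  stringsAsFactors = FALSE)
  if (!all(v$occupied %in% c(0L, 1L))) stop("'occupied' must be 0/1")
  v <- v[order(v$box_id, v$year, v$date), ]
  first <- !duplicated(v[c("box_id", "year")])
  n_dup <- sum(!first)
  v <- v[first, ]
  late <- v$month > last_month
  n_late <- sum(late)
  v <- v[!late, ]
  message("first_visit_filter: dropped ", n_dup, " repeat visit(s) and ",
          n_late, " box-year(s) first checked after month ", last_month)
  rownames(v) <- NULL
  v[c("box_id", "year", "occupied")]
}

#' Standardize a covariate
#'
#' Centres and scales to sample mean 0 and sample SD 1 (n - 1 denominator),
#' recording the transform in attributes `center` and `scale` so it can be
#' reapplied to new data.
#'
#' @param x numeric vector with at least two distinct values.
#' @param name covariate name used in error messages.
#' @return standardized numeric vector with `center`/`scale` attributes.
#' @export
standardize <- function(x, name = deparse(substitute(x))) {
  if (length(unique(x[is.finite(x)])) < 2L)
    stop("cannot standardize '", name, "': zero variance")
  m <- mean(x)
  s <- stats::sd(x)
  structure((x - m) / s, center = m, scale = s)
}

#' Standardize several columns of a data frame
#'
#' @param data data frame.
#' @param cols column names to standardize in place.
#' @return `data` with standardized columns; the transforms are stored in
#'   `attr(, "scaling")` as a data frame (`term`, `center`, `scale`).
#' @export
standardize_columns <- function(data, cols) {
  missing <- setdiff(cols, names(data))
  if (length(missing)) stop("column(s) not found: ", paste(missing, collapse = ", "))
  sc <- data.frame(term = cols, center = NA_real_, scale = NA_real_,
                   stringsAsFactors = FALSE)
  for (i in seq_along(cols)) {
    z <- standardize(data[[cols[i]]], name = cols[i])
    sc$center[i] <- attr(z, "center")
    sc$scale[i] <- attr(z, "scale")
    data[[cols[i]]] <- as.numeric(z)
  }
  attr(data, "scaling") <- sc
  data
}

#' Add a quadratic term built from a standardized parent
#'
#' Squares an already-standardized column; the new column is named
#' `<term>^2` and is not itself re-standardized.
#'
#' @param data data frame.
#' @param term name of the standardized parent column.
#' @return `data` with the added `` `<term>^2` `` column.
#' @export
add_quadratic <- function(data, term) {
  if (!term %in% names(data)) stop("term '", term, "' not found")
  x <- data[[term]]
  q <- x^2
  if (stats::var(q) < 1e-10)
    warning("quadratic of '", term, "' is near-constant")
  data[[paste0(term, "^2")]] <- q
  data
}

#' Variance inflation factors
#'
#' VIF of each variable: `1 / (1 - R^2)` from the least-squares regression
#' of that column on all the others plus an intercept. Intended for
#' main-effect columns only (quadratics and interactions inflate VIF
#' trivially). Perfectly collinear variables get `Inf`.
#'
#' @param data data frame holding the columns.
#' @param variables names of the columns to assess (>= 2).
#' @return object of class `vif_report`: data frame (`variable`, `vif`) plus
#'   attributes `threshold` and `dropped`.
#' @export
compute_vif <- function(data, variables) {
  if (length(variables) < 2L) stop("need at least two variables for VIF")
  missing <- setdiff(variables, names(data))
  if (length(missing)) stop("column(s) not found: ", paste(missing, collapse = ", "))
  X <- as.matrix(data[variables])
  vif <- vapply(seq_along(variables), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r <- fit$residuals
    tot <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - sum(r^2) / tot
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  structure(data.frame(variable = variables, vif = vif, stringsAsFactors = FALSE),
            threshold = NA_real_, dropped = character(0), class = c("vif_report", "data.frame"))
}

#' Iterative VIF screening
#'
#' Repeatedly removes the variable with the largest VIF until all remaining
#' VIFs fall below the threshold. Exempt (mandatory) variables are never
#' removed.
#'
#' @param data data frame holding the columns.
#' @param variables candidate main-effect columns.
#' @param threshold VIF threshold (default 5, > 1).
#' @param exempt variables protected from removal.
#' @return a `vif_report` for the retained set, with attributes `dropped`
#'   (in removal order), `retained` and `threshold`.
#' @export
vif_screen <- function(data, variables, threshold = 5, exempt = character(0)) {
  if (threshold <= 1) stop("'threshold' must exceed 1")
  vars <- variables
  dropped <- character(0)
  repeat {
    rep <- compute_vif(data, vars)
    worst <- order(-rep$vif)
    if (max(rep$vif) < threshold) break
    removable <- setdiff(rep$variable[worst][rep$vif[worst] >= threshold], exempt)
    if (!length(removable))
      stop("VIF screening cannot reach threshold ", threshold,
           ": only exempt variables remain above it")
    drop <- removable[1]
    dropped <- c(dropped, drop)
    vars <- setdiff(vars, drop)
    if (length(vars) < 2L || !length(setdiff(vars, exempt)))
      stop("VIF screening would empty the candidate variable set")
  }
  attr(rep, "threshold") <- threshold
  attr(rep, "dropped") <- dropped
  attr(rep, "retained") <- vars
  rep
}

#' @export
print.vif_report <- function(x, ...) {
  cat("variance inflation factors\n")
  print.data.frame(x, row.names = FALSE)
  dropped <- attr(x, "dropped")
  if (length(dropped)) cat("dropped (in order):", paste(dropped, collapse = ", "), "\n")
  if (!is.na(attr(x, "threshold"))) cat("threshold:", attr(x, "threshold"), "\n")
  invisible(x)
}
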