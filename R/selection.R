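#' Exhaustive best-subset model ranking by AIC
#'
#' Enumerates every subset of the optional main-effect terms (mandatory
#' terms always included; a quadratic term enters if and only if its parent
#' does), fits each candidate with [occu_glmm()] and ranks by AIC. Ties are
#' broken toward fewer terms, then lexicographic term order.
#'
#' @param response response column name.
#' @param data box-year data frame with all columns standardized as needed.
#' @param mandatory terms forced into every candidate (may be empty).
#' @param optional candidate main-effect terms (at most 20).
#' @param random random-intercept specification, see [occu_glmm()].
#' @param quadratics named character vector mapping a parent term to its
#'   quadratic column, e.g. `c(Field = "Field^2")`.
#' @param top_k number of best models to return (default 10).
#' @param ... passed to [occu_glmm()].
#' @return object of class `model_ranking`: data frame with `model` (term
#'   list), `n_terms`, `AIC`, `delta_aic`, `converged`; the full candidate
#'   count is in `attr(, "n_candidates")`.
#' @export
best_subset_search <- function(response, data, mandatory, optional, random,
                               quadratics = NULL, top_k = 10, ...) {
  m <- length(optional)
  if (m > 20)
    stop("more than 20 optional terms (", m, "): exhaustive enumeration is ",
         "intractable; reduce the candidate term set")
  n_cand <- 2^m
  rows <- vector("list", n_cand)
  for (i in seq_len(n_cand) - 1L) {
    sel <- optional[bitwAnd(i, bitwShiftL(1L, seq_len(m) - 1L)) > 0L]
    terms <- c(mandatory, sel)
    for (parent in intersect(names(quadratics), sel))
      terms <- c(terms, quadratics[[parent]])
    fit <- tryCatch(
      occu_glmm(occu_formula(response, terms), data = data, random = random, ...),
      error = function(e) NULL)
    rows[[i + 1L]] <- data.frame(
      model = if (length(sel)) paste(sort(sel), collapse = " + ") else "(mandatory only)",
      n_terms = length(sel),
      AIC = if (is.null(fit)) NA_real_ else fit$aic,
      converged = if (is.null(fit)) FALSE else fit$converged,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  ok <- tab[tab$converged & is.finite(tab$AIC), ]
  if (!nrow(ok)) stop("best-subset search: no candidate model converged")
  ok <- ok[order(ok$AIC, ok$n_terms, ok$model), ]
  ok$delta_aic <- ok$AIC - ok$AIC[1]
  out <- utils::head(ok, top_k)
  rownames(out) <- NULL
  structure(out, n_candidates = n_cand, class = c("model_ranking", "data.frame"))
}

#' @export
print.model_ranking <- function(x, ...) {
  cat("top", nrow(x), "of", attr(x, "n_candidates"), "candidate models by AIC\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Predator-by-habitat interaction analysis
#'
#' Adds the products of a risk term with preferred and non-preferred
#' habitat terms (built from the standardized parent columns, not
#' re-standardized) to the home-range-scale model, then drops interactions
#' that are not significant at `alpha` and refits. Both the full and the
#' final fits are returned.
#'
#' @param formula fixed-effects formula of the base model (parents of every
#'   interaction must appear in it).
#' @param data box-year data frame with standardized parent columns.
#' @param random random-intercept specification, see [occu_glmm()].
#' @param pairs list of length-2 character vectors naming the parent
#'   columns of each interaction, e.g. `list(c("risk", "Mo spruce"))`.
#' @param alpha two-sided Wald significance level for retention.
#' @param ... passed to [occu_glmm()].
#' @return list with `full` and `final` fits, `retained` and `dropped`
#'   interaction column names, and the full-model `table`.
#' @export
interaction_analysis <- function(formula, data, random, pairs, alpha = 0.05, ...) {
  int_names <- character(0)
  for (pr in pairs) {
    if (length(pr) != 2L) stop("each interaction pair must name two columns")
    miss <- setdiff(pr, names(data))
    if (length(miss)) stop("interaction parent(s) not found: ",
                           paste(miss, collapse = ", "))
    nm <- paste(pr, collapse = ":")
    col <- data[[pr[1]]] * data[[pr[2]]]
    if (stats::var(col) < 1e-12)
      stop("interaction '", nm, "' is rank-deficient: product column has zero variance")
    data[[nm]] <- col
    int_names <- c(int_names, nm)
  }
  resp <- deparse(formula[[2]])
  rhs <- paste(deparse(formula[[3]]), collapse = " ")
  bt <- function(x) paste0("`", x, "`")
  full_f <- stats::as.formula(paste(resp, "~", rhs, "+",
                                    paste(bt(int_names), collapse = " + ")))
  full <- occu_glmm(full_f, data = data, random = random, ...)
  tab <- full$coefficients
  ptab <- tab[match(int_names, tab$term), ]
  if (anyNA(ptab$p)) {
    warning("interaction term(s) not estimable in the full model: ",
            paste(int_names[is.na(ptab$p)], collapse = ", "),
            " (treated as dropped)")
  }
  retained <- int_names[!is.na(ptab$p) & ptab$p < alpha]
  dropped <- setdiff(int_names, retained)
  final <- if (length(dropped)) {
    f2 <- if (length(retained))
      stats::as.formula(paste(resp, "~", rhs, "+", paste(bt(retained), collapse = " + ")))
    else stats::as.formula(paste(resp, "~", rhs))
    occu_glmm(f2, data = data, random = random, ...)
  } else full
  list(full = full, final = final, retained = retained, dropped = dropped,
       table = tab)
}

#' Cone-crop by forest-type interaction models
#'
#' Fits the two food-availability models for red squirrels: previous-autumn
#' spruce cone index crossed with the area of spruce forest, and with the
#' area of pine forest, each with the cone and forest main effects, a
#' site-level random intercept, and any additional base terms. The cone
#' index of year `y - 1` is joined to occupancy year `y`; cone and forest
#' columns are standardized before the product is formed.
#'
#' @param occ box-year data frame with the response, `year`, grouping
#'   columns and (raw or standardized) forest-area columns.
#' @param cone_index data frame `year`, `crop` (yearly cone index).
#' @param response response column name.
#' @param spruce_col,pine_col forest-area column names.
#' @param base_terms additional fixed-effect terms (e.g. standardized year,
#'   time period).
#' @param random random-intercept specification (default site only).
#' @param ... passed to [occu_glmm()].
#' @return list of two [occu_glmm()] fits, `spruce` and `pine`, each with
#'   terms `cone`, the forest column, and their product.
#' @export
cone_models <- function(occ, cone_index, response = "occupied",
                        spruce_col = "Mo spruce", pine_col = "Mo pine",
                        base_terms = character(0), random = ~site_id, ...) {
  need <- sort(unique(occ$year)) - 1L
  miss <- setdiff(need, cone_index$year)
  if (length(miss))
    stop("missing cone index for lag year(s): ", paste(miss, collapse = ", "))
  cone_raw <- cone_index$crop[match(occ$year - 1L, cone_index$year)]
  if (length(unique(cone_raw)) < 2L)
    stop("cannot standardize 'cone': zero variance across analysis years")
  occ$cone <- as.numeric(standardize(cone_raw, name = "cone"))
  fit_one <- function(forest_col) {
    if (!forest_col %in% names(occ)) stop("column '", forest_col, "' not found")
    x <- occ[[forest_col]]
    if (stats::var(x) < 1e-12)
      stop("rank-deficient: forest column '", forest_col, "' has zero variance")
    occ[[forest_col]] <- as.numeric(standardize(x, name = forest_col))
    nm <- paste0("cone:", forest_col)
    occ[[nm]] <- occ$cone * occ[[forest_col]]
    f <- occu_formula(response, c(base_terms, "cone", forest_col, nm))
    occu_glmm(f, data = occ, random = random, ...)
  }
  list(spruce = fit_one(spruce_col), pine = fit_one(pine_col))
}
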