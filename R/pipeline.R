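#' Pipeline configuration
#'
#' Paths, species-specific scales, kernel candidate lists and analysis
#' settings for [run_pipeline()]. The input directory must hold the layout
#' written by [write_study()] (or equivalently formatted user data):
#' `grid.asc`, `boxes.csv`, `visits.csv`, `predators.csv` and, for red
#' squirrel analyses, `cones.csv`.
#'
#' @param input_dir directory with the input files.
#' @param out_dir directory for the report bundle (created if needed).
#' @param species `"flying"` or `"red"`.
#' @param years analysis years; `NULL` uses every year in the cleaned data.
#' @param buffer_small,buffer_large buffer radii (m); defaults 200/1000
#'   (flying) and 300/2500 (red).
#' @param predators predator species searched over; defaults
#'   `c("ural_owl", "goshawk")` for flying and `"goshawk"` for red.
#' @param sd_m,flat_top_m,lags kernel candidate lists.
#' @param cutoff_m kernel truncation distance (m).
#' @param aggregation kernel aggregation over nests.
#' @param vif_threshold VIF screening threshold (default 5).
#' @param alpha two-sided significance level (default 0.05).
#' @param moran_radii Moran's I neighbourhood radii (m).
#' @param subset_terms optional-term universe of the best-subset search;
#'   `NULL` uses the a-priori terms of interest (main risk, Field,
#'   Mo spruce, Built).
#' @param top_k number of best models reported.
#' @param seed integer seed (the pipeline itself is deterministic; the seed
#'   is recorded in the manifest and used by any optional permutation test).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, out_dir, species = c("flying", "red"),
                            years = NULL,
                            buffer_small = NULL, buffer_large = NULL,
                            predators = NULL,
                            sd_m = c(1000, 2000, 3000, 4000),
                            flat_top_m = c(500, 1000, 1500, 2000, 2500),
                            lags = c(0, 1), cutoff_m = 10000,
                            aggregation = c("sum", "max"),
                            vif_threshold = 5, alpha = 0.05,
                            moran_radii = c(50, 500, 5000),
                            subset_terms = NULL, top_k = 10, seed = 1) {
  species <- match.arg(species)
  aggregation <- match.arg(aggregation)
  flying <- species == "flying"
  if (is.null(buffer_small)) buffer_small <- if (flying) 200 else 300
  if (is.null(buffer_large)) buffer_large <- if (flying) 1000 else 2500
  if (is.null(predators)) predators <- if (flying) c("ural_owl", "goshawk") else "goshawk"
  if (buffer_small <= 0 || buffer_large <= 0) stop("buffer radii must be positive")
  if (!length(sd_m) || !length(flat_top_m) || !length(lags))
    stop("kernel candidate lists must be non-empty")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  structure(list(input_dir = input_dir, out_dir = out_dir, species = species,
                 years = years, buffer_small = buffer_small,
                 buffer_large = buffer_large, predators = predators,
                 sd_m = sd_m, flat_top_m = flat_top_m, lags = lags,
                 cutoff_m = cutoff_m, aggregation = aggregation,
                 vif_threshold = vif_threshold, alpha = alpha,
                 moran_radii = moran_radii, subset_terms = subset_terms,
                 top_k = top_k, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full occupancy analysis pipeline
#'
#' Executes the study workflow on one input set: visit cleaning, habitat
#' composition at both scales, VIF screening of the habitat covariates,
#' AIC kernel/lag selection per predator, full mixed occupancy models at
#' both scales, dedicated young-pine models, predator-by-habitat
#' interaction analysis at the home-range scale, cone-crop models (red
#' squirrel), a best-subset AIC ranking, and Moran's I residual
#' diagnostics. Every stage writes its outputs as plain CSV into
#' `config$out_dir` as soon as it completes, so a failing stage leaves the
#' earlier outputs intact; errors are re-raised with the stage name. The
#' run is a pure function of the inputs and configuration.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the fitted models and tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out, "pipeline_log.txt")
  cat("", file = logfile)
  log_line <- function(stage, msg)
    cat(sprintf("[%s] INFO %s\n", stage, msg), file = logfile, append = TRUE)
  with_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  res <- list()
  flying <- config$species == "flying"
  random <- if (flying) c("site_id", "box_id") else "site_id"
  main_pred <- config$predators[1]
  risk_col <- function(sp) paste0("risk_", sp)

  # -- clean ----------------------------------------------------------------
  clean <- with_stage("clean", {
    boxes <- utils::read.csv(file.path(config$input_dir, "boxes.csv"),
                             stringsAsFactors = FALSE, check.names = FALSE)
    visits <- utils::read.csv(file.path(config$input_dir, "visits.csv"),
                              stringsAsFactors = FALSE, check.names = FALSE)
    occ <- suppressMessages(first_visit_filter(visits))
    if (!is.null(config$years)) occ <- occ[occ$year %in% config$years, ]
    occ <- merge(occ, boxes[c("box_id", "site_id", "x", "y")], by = "box_id")
    occ <- occ[order(occ$box_id, occ$year), ]
    rownames(occ) <- NULL
    utils::write.csv(occ, file.path(out, "clean_occupancy.csv"), row.names = FALSE)
    log_line("clean", sprintf("%d box-years across %d boxes", nrow(occ),
                              length(unique(occ$box_id))))
    list(occ = occ, boxes = boxes)
  })
  occ <- clean$occ
  boxes <- clean$boxes
  years <- sort(unique(occ$year))

  # -- habitat --------------------------------------------------------------
  hab <- with_stage("habitat", {
    grid <- read_grid(file.path(config$input_dir, "grid.asc"))
    merged <- merge_classes(grid)
    small <- habitat_composition(merged, boxes, config$buffer_small)
    large <- habitat_composition(merged, boxes, config$buffer_large)
    utils::write.csv(small, file.path(out, "habitat_small.csv"), row.names = FALSE)
    utils::write.csv(large, file.path(out, "habitat_large.csv"), row.names = FALSE)
    log_line("habitat", sprintf("compositions at %g and %g m for %d boxes",
                                config$buffer_small, config$buffer_large,
                                nrow(boxes)))
    list(small = habitat_wide(small), large = habitat_wide(large))
  })

  build_design <- function(wide) {
    d <- merge(occ, wide, by = "box_id")
    d <- d[order(d$box_id, d$year), ]
    classes <- setdiff(names(wide), "box_id")
    keep <- classes[vapply(classes, function(cl) stats::var(d[[cl]]) > 0, logical(1))]
    if (length(keep) < length(classes))
      log_line("habitat", paste("zero-variance class(es) dropped:",
                                paste(setdiff(classes, keep), collapse = ", ")))
    d <- standardize_columns(d, keep)
    d$year_std <- as.numeric(standardize(d$year, name = "year"))
    if (!flying) d$time_period2 <- as.numeric(d$year >= 2006)
    list(data = d, classes = keep)
  }

  # -- vif ------------------------------------------------------------------
  vif <- with_stage("vif", {
    screen_one <- function(wide, label) {
      b <- build_design(wide)
      rep <- vif_screen(b$data, b$classes, threshold = config$vif_threshold,
                        exempt = intersect(c("Field", "Mo spruce"), b$classes))
      utils::write.csv(
        data.frame(scale = label, rep, stringsAsFactors = FALSE),
        file.path(out, paste0("vif_", label, ".csv")), row.names = FALSE)
      log_line("vif", sprintf("%s scale: dropped [%s], retained %d classes",
                              label, paste(attr(rep, "dropped"), collapse = ", "),
                              length(attr(rep, "retained"))))
      list(design = b, retained = attr(rep, "retained"), report = rep)
    }
    list(small = screen_one(hab$small, "small"),
         large = screen_one(hab$large, "large"))
  })

  base_terms_of <- function(retained)
    c("year_std", if (!flying) "time_period2", retained,
      if ("Field" %in% retained) "Field^2")
  d_small <- add_quadratic(vif$small$design$data, "Field")
  d_large <- add_quadratic(vif$large$design$data, "Field")

  # -- select-kernel --------------------------------------------------------
  kernels <- with_stage("select-kernel", {
    nests <- utils::read.csv(file.path(config$input_dir, "predators.csv"),
                             stringsAsFactors = FALSE, check.names = FALSE)
    sel <- list()
    for (sp in config$predators) {
      nsp <- nests[nests$species == sp, , drop = FALSE]
      if (!nrow(nsp)) stop("no nests for predator '", sp, "'")
      ks <- select_kernel(
        d_small, boxes, nsp,
        formula = occu_formula("occupied", base_terms_of(vif$small$retained)),
        random = random, sd_m = config$sd_m, flat_top_m = config$flat_top_m,
        lags = config$lags, cutoff_m = config$cutoff_m,
        aggregation = config$aggregation, risk_name = risk_col(sp),
        quadratic = flying && sp == "goshawk")
      utils::write.csv(ks$table, file.path(out, paste0("kernel_search_", sp, ".csv")),
                       row.names = FALSE)
      log_line("select-kernel",
               sprintf("%s: SD %g m, flat top %g m, lag %d (delta AIC %.2f)",
                       sp, ks$best$sd_m, ks$best$flat_top_m, ks$best_lag,
                       ks$delta_aic))
      sel[[sp]] <- ks
    }
    # attach the selected risk covariates (standardized) to both designs
    attach_risk <- function(d) {
      for (sp in config$predators) {
        rc <- suppressMessages(risk_covariate(
          boxes, nests[nests$species == sp, ], sel[[sp]]$best, years,
          lag = sel[[sp]]$best_lag, aggregation = config$aggregation))
        v <- rc$value[match(paste(d$box_id, d$year), paste(rc$box_id, rc$year))]
        d[[risk_col(sp)]] <- as.numeric(standardize(v, name = risk_col(sp)))
        if (flying && sp == "goshawk")
          d[[paste0(risk_col(sp), "^2")]] <- d[[risk_col(sp)]]^2
      }
      d
    }
    d_small <- attach_risk(d_small)
    d_large <- attach_risk(d_large)
    sel
  })

  risk_terms <- c(risk_col(main_pred),
                  if (flying && "goshawk" %in% config$predators)
                    c(risk_col("goshawk"), paste0(risk_col("goshawk"), "^2")))
  risk_terms <- unique(risk_terms)

  # -- fit ------------------------------------------------------------------
  fits <- with_stage("fit", {
    fit_scale <- function(d, retained, label) {
      f <- occu_formula("occupied", c(base_terms_of(retained), risk_terms))
      fit <- occu_glmm(f, data = d, random = random)
      utils::write.csv(wald_table(fit, alpha = config$alpha),
                       file.path(out, paste0("coef_", label, ".csv")),
                       row.names = FALSE)
      log_line("fit", sprintf("%s scale: n = %d, AIC = %.2f, converged = %s",
                              label, fit$n_obs, fit$aic, fit$converged))
      fit
    }
    small <- fit_scale(d_small, vif$small$retained, "small")
    large <- fit_scale(d_large, vif$large$retained, "large")
    summ <- list(
      small = list(logLik = small$loglik, AIC = small$aic, df = small$df,
                   n = small$n_obs, converged = small$converged,
                   re_sd = as.list(small$re_sd)),
      large = list(logLik = large$loglik, AIC = large$aic, df = large$df,
                   n = large$n_obs, converged = large$converged,
                   re_sd = as.list(large$re_sd)))
    jsonlite::write_json(summ, file.path(out, "fit_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    list(small = small, large = large)
  })

  # -- young-pine -----------------------------------------------------------
  ypine <- with_stage("young-pine", {
    fit_yp <- function(d, label) {
      if (!"Y pine" %in% names(d)) stop("no 'Y pine' column at ", label, " scale")
      f <- occu_formula("occupied",
                        c("year_std", if (!flying) "time_period2",
                          risk_terms, "Y pine"))
      occu_glmm(f, data = d, random = random)
    }
    yp <- list(small = fit_yp(d_small, "small"), large = fit_yp(d_large, "large"))
    tab <- do.call(rbind, lapply(names(yp), function(nm)
      data.frame(scale = nm, wald_table(yp[[nm]], alpha = config$alpha),
                 stringsAsFactors = FALSE)))
    utils::write.csv(tab, file.path(out, "young_pine_models.csv"), row.names = FALSE)
    log_line("young-pine", "dedicated young-pine models fitted at both scales")
    yp
  })

  # -- interactions ---------------------------------------------------------
  inter <- with_stage("interactions", {
    d <- d_small
    preferred <- "Mo spruce"
    nonpref <- "Y pine"
    need <- intersect(c(preferred, nonpref), vif$small$retained)
    extra <- setdiff(c(preferred, nonpref), c(base_terms_of(vif$small$retained)))
    f <- occu_formula("occupied",
                      c(base_terms_of(vif$small$retained), risk_terms, extra))
    ia <- interaction_analysis(
      f, data = d, random = random,
      pairs = list(c(risk_col(main_pred), preferred),
                   c(risk_col(main_pred), nonpref)),
      alpha = config$alpha)
    utils::write.csv(ia$table, file.path(out, "interaction_full.csv"),
                     row.names = FALSE)
    utils::write.csv(wald_table(ia$final, alpha = config$alpha),
                     file.path(out, "interaction_final.csv"), row.names = FALSE)
    log_line("interactions",
             sprintf("retained: %s", if (length(ia$retained))
               paste(ia$retained, collapse = ", ") else "(none)"))
    ia
  })

  # -- cones (red squirrel) -------------------------------------------------
  cones <- if (!flying) with_stage("cones", {
    cone_path <- file.path(config$input_dir, "cones.csv")
    if (!file.exists(cone_path)) stop("cone index file not found: ", cone_path)
    cone_index <- utils::read.csv(cone_path, stringsAsFactors = FALSE)
    cm <- cone_models(d_small, cone_index,
                      base_terms = c("year_std", "time_period2"),
                      random = "site_id")
    tab <- do.call(rbind, lapply(names(cm), function(nm)
      data.frame(model = nm, wald_table(cm[[nm]], alpha = config$alpha),
                 stringsAsFactors = FALSE)))
    utils::write.csv(tab, file.path(out, "cone_models.csv"), row.names = FALSE)
    log_line("cones", "cone-by-forest interaction models fitted")
    cm
  }) else NULL

  # -- best-subset ----------------------------------------------------------
  ranking <- with_stage("best-subset", {
    optional <- config$subset_terms
    if (is.null(optional))
      optional <- unique(c(risk_col(main_pred),
                           intersect(c("Field", "Mo spruce", "Built"),
                                     vif$small$retained)))
    rk <- best_subset_search(
      "occupied", data = d_small,
      mandatory = c("year_std", if (!flying) "time_period2"),
      optional = optional, random = random,
      quadratics = if ("Field" %in% optional) c("Field" = "Field^2"),
      top_k = config$top_k)
    utils::write.csv(as.data.frame(rk), file.path(out, "model_ranking.csv"),
                     row.names = FALSE)
    log_line("best-subset", sprintf("%d candidates, best: %s",
                                    attr(rk, "n_candidates"), rk$model[1]))
    rk
  })

  # -- moran ----------------------------------------------------------------
  moran <- with_stage("moran", {
    mr <- list(small = moran_diagnostics(fits$small, d_small,
                                         radii = config$moran_radii),
               large = moran_diagnostics(fits$large, d_large,
                                         radii = config$moran_radii))
    tab <- do.call(rbind, lapply(names(mr), function(nm)
      data.frame(scale = nm, mr[[nm]], stringsAsFactors = FALSE)))
    utils::write.csv(tab, file.path(out, "moran.csv"), row.names = FALSE)
    log_line("moran", sprintf("radii %s m", paste(config$moran_radii, collapse = "/")))
    tab
  })

  # -- manifest -------------------------------------------------------------
  with_stage("report", {
    cfg <- config
    cfg$input_dir <- NULL  # paths vary across machines and reruns
    cfg$out_dir <- NULL
    writeLines(c("riskscape pipeline manifest",
                 utils::capture.output(utils::str(unclass(cfg)))),
               file.path(out, "manifest.txt"))
  })

  invisible(list(config = config, clean = occ, vif = vif, kernels = kernels,
                 fits = fits, young_pine = ypine, interactions = inter,
                 cones = cones, ranking = ranking, moran = moran,
                 design_small = d_small, design_large = d_large))
}
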