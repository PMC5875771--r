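#' Configuration of a synthetic nest-box study
#'
#' Bundles every generator truth: landscape mixture and clustering, site and
#' box geometry, predator territory process, kernel truth, true
#' coefficients on the log-odds scale, random-intercept SDs, and the cone
#' series. Defaults emulate the two monitoring programmes: the flying
#' squirrel programme (2002--2015, two boxes 80--100 m apart per site,
#' Ural owl as main predator at lag 1) and the red squirrel programme
#' (1999--2015, one box per site, goshawk at lag 0, detection-period factor,
#' cone-crop terms).
#'
#' True coefficients default to the magnitudes reported for the field
#' system: flying squirrel risk -2.4, field 0.71, field^2 -0.23, year 0.26;
#' red squirrel cone 0.17 and cone-by-spruce 0.08, among others.
#'
#' @param species `"flying"` or `"red"`.
#' @param seed master integer seed; all component streams derive from it.
#' @param n_sites number of forest sites.
#' @param years analysis years.
#' @param extent_m side of the square landscape (m); computed from the site
#'   packing requirement when `NULL`.
#' @param cell_size_m raster resolution (default 25 m).
#' @param margin_m landscape margin kept free of sites so buffers never
#'   truncate; defaults to the large buffer radius.
#' @param class_mix named vector of target class proportions (sums to 1).
#' @param clustering_range_m spatial correlation range of land use (m).
#' @param boxes_per_site 2 (flying) or 1 (red).
#' @param box_spacing_m range of within-site box spacing (m).
#' @param min_site_spacing_m hard-core minimum distance between sites (m).
#' @param predator_density nests per 10 km^2, named by predator species.
#' @param territory_persistence probability a nest location is reused the
#'   next year.
#' @param kernel_truth a [kernel_params()]: the true risk kernel.
#' @param kernel_lag true lag (0 or 1) of the risk effect.
#' @param aggregation kernel aggregation over nests, `"sum"` or `"max"`.
#' @param main_predator predator species whose kernel drives occupancy.
#' @param beta named vector of true log-odds coefficients; names refer to
#'   `"(Intercept)"`, `"year"`, `"risk"`, habitat class labels, `"<x>^2"`
#'   quadratics, `"cone"`, `"cone:<class>"` products and `"time_period2"`.
#' @param sigma_site,sigma_box random-intercept SDs.
#' @param buffer_small,buffer_large buffer radii (m) for the two scales.
#' @param cone generator parameters of the yearly cone index: a log-normal
#'   baseline with occasional mast years (`meanlog`, `sdlog`, `mast_prob`,
#'   `mast_meanlog`, `mast_sdlog`).
#' @param cone_series optional data frame `year`, `crop` overriding the
#'   generator.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(species = c("flying", "red"), seed = 1,
                       n_sites = NULL, years = NULL,
                       extent_m = NULL, cell_size_m = 25, margin_m = NULL,
                       class_mix = NULL, clustering_range_m = 1500,
                       boxes_per_site = NULL, box_spacing_m = c(80, 100),
                       min_site_spacing_m = 800,
                       predator_density = c(ural_owl = 2, goshawk = 1),
                       territory_persistence = 0.85,
                       kernel_truth = NULL, kernel_lag = NULL,
                       aggregation = c("sum", "max"),
                       main_predator = NULL,
                       beta = NULL, sigma_site = 1, sigma_box = NULL,
                       buffer_small = NULL, buffer_large = NULL,
                       cone = list(meanlog = 0, sdlog = 0.6, mast_prob = 0.25,
                                   mast_meanlog = 1.5, mast_sdlog = 0.3),
                       cone_series = NULL) {
  species <- match.arg(species)
  aggregation <- match.arg(aggregation)
  flying <- species == "flying"
  if (is.null(years)) years <- if (flying) 2002:2015 else 1999:2015
  if (is.null(n_sites)) n_sites <- if (flying) 290 else 560
  if (is.null(boxes_per_site)) boxes_per_site <- if (flying) 2L else 1L
  if (is.null(sigma_box)) sigma_box <- if (flying) 0.5 else 0
  if (is.null(kernel_truth))
    kernel_truth <- if (flying) kernel_params(3000, 2500) else kernel_params(1000, 500)
  if (is.null(kernel_lag)) kernel_lag <- if (flying) 1L else 0L
  if (is.null(main_predator)) main_predator <- if (flying) "ural_owl" else "goshawk"
  if (is.null(buffer_small)) buffer_small <- if (flying) 200 else 300
  if (is.null(buffer_large)) buffer_large <- if (flying) 1000 else 2500
  if (is.null(beta)) {
    beta <- if (flying)
      c("(Intercept)" = -2.2, year = 0.26, risk = -2.4,
        "Field" = 0.71, "Field^2" = -0.23)
    else
      c("(Intercept)" = -2.27, year = -0.16, time_period2 = 1.33, risk = -0.32,
        "Field" = 0.36, "Field^2" = -0.08, cone = 0.17, "cone:Mo spruce" = 0.08)
  }
  if (is.null(class_mix))
    class_mix <- c("Clear cut" = 0.08, "Y birch" = 0.08, "Y pine" = 0.10,
                   "Y mix" = 0.10, "Mo birch" = 0.05, "Mo pine" = 0.11,
                   "Mo spruce" = 0.12, "Mo birch pine" = 0.05,
                   "Mo pine spruce" = 0.08, "Mo birch spruce" = 0.05,
                   "Built" = 0.02, "Bog" = 0.06, "Field" = 0.10)
  if (abs(sum(class_mix) - 1) > 1e-6)
    stop("'class_mix' proportions must sum to 1")
  if (is.null(margin_m)) margin_m <- buffer_large
  if (is.null(extent_m)) {
    # hard-core packing restricted to forest cells stalls well below disc
    # saturation; 3.5 exclusion areas per site keeps rejection sampling fast
    inner <- sqrt(n_sites * min_site_spacing_m^2 * 3.5)
    extent_m <- ceiling((inner + 2 * margin_m) / 1000) * 1000
  }
  inner_side <- extent_m - 2 * margin_m
  if (inner_side^2 < n_sites * min_site_spacing_m^2 * 2.0)
    stop("cannot place ", n_sites, " sites at >= ", min_site_spacing_m,
         " m spacing inside a ", extent_m, " m extent with ", margin_m,
         " m margin; enlarge 'extent_m'")
  if (!kernel_lag %in% c(0, 1)) stop("'kernel_lag' must be 0 or 1")
  structure(list(
    species = species, seed = as.integer(seed), n_sites = n_sites,
    years = as.integer(years), extent_m = extent_m, cell_size_m = cell_size_m,
    margin_m = margin_m, class_mix = class_mix,
    clustering_range_m = clustering_range_m, boxes_per_site = boxes_per_site,
    box_spacing_m = box_spacing_m, min_site_spacing_m = min_site_spacing_m,
    predator_density = predator_density,
    territory_persistence = territory_persistence,
    kernel_truth = kernel_truth, kernel_lag = as.integer(kernel_lag),
    aggregation = aggregation, main_predator = main_predator, beta = beta,
    sigma_site = sigma_site, sigma_box = sigma_box,
    buffer_small = buffer_small, buffer_large = buffer_large,
    cone = cone, cone_series = cone_series
  ), class = "sim_config")
}

# independent, reproducible seed per generator component
component_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k * 9973) %% 2147483629)
}

forest_classes <- function() {
  c("Y birch", "Y pine", "Y mix", "Mo birch", "Mo pine", "Mo spruce",
    "Mo birch pine", "Mo pine spruce", "Mo birch spruce")
}

# representative raw code per merged class (so generated grids exercise
# the merge step)
raw_code_of <- function(class) {
  tab <- default_class_table()
  vapply(class, function(cl) tab$raw_code[match(cl, tab$class)], integer(1))
}

#' Generate a clustered categorical landscape
#'
#' Draws one smooth Gaussian random field per class (white noise smoothed
#' by a Gaussian filter of range `clustering_range_m`, via FFT) and assigns
#' each cell to the class maximizing `field + offset`, where the offsets
#' start at the log target shares and are calibrated iteratively until the
#' empirical class shares match the target mix (within half a percentage
#' point, well inside the 3-point contract at study extents). Patch size is
#' controlled by the field correlation range; any pair of classes can share
#' boundaries. Cells carry raw land-use codes (one representative code per
#' merged class).
#'
#' @param config a [sim_config()].
#' @return a raw-code [land_grid()].
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(component_seed(config$seed, 1L))
  n <- as.integer(round(config$extent_m / config$cell_size_m))
  mix <- config$class_mix
  codes <- raw_code_of(names(mix))
  if (any(mix >= 1 - 1e-12)) {
    cells <- matrix(codes[which.max(mix)], n, n)
    return(land_grid(cells, 0, 0, config$cell_size_m))
  }
  K <- length(mix)
  range_cells <- config$clustering_range_m / config$cell_size_m
  smooth_kernel <- NULL
  if (range_cells > 0) {
    ax <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))  # wrap-around lags
    g1 <- exp(-ax^2 / (2 * (range_cells / 2)^2))
    smooth_kernel <- stats::fft(outer(g1, g1) / sum(outer(g1, g1)))
  }
  F <- matrix(0, n * n, K)
  for (k in seq_len(K)) {
    z <- matrix(stats::rnorm(n * n), n, n)
    if (!is.null(smooth_kernel))
      z <- Re(stats::fft(stats::fft(z) * smooth_kernel, inverse = TRUE)) / (n * n)
    F[, k] <- as.vector(z) / stats::sd(z)
  }
  off <- log(mix)
  best <- off
  best_err <- Inf
  for (it in 1:400) {
    idx <- max.col(F + rep(off, each = n * n), ties.method = "first")
    emp <- tabulate(idx, nbins = K) / (n * n)
    err <- max(abs(emp - mix))
    if (err < best_err) {
      best_err <- err
      best <- off
    }
    if (err < 0.004) break
    off <- off + 0.5 * 0.995^it * (log(mix) - log(pmax(emp, 1e-4)))
  }
  idx <- max.col(F + rep(best, each = n * n), ties.method = "first")
  cells <- matrix(codes[idx], n, n)
  land_grid(cells, 0, 0, config$cell_size_m)
}

#' Place study sites and nest boxes
#'
#' Site centres are drawn by hard-core inhibition (uniform proposals on
#' forest cells inside the margin, rejected within `min_site_spacing_m` of
#' an accepted site). In paired-box designs the second box sits at a
#' uniform random bearing at a distance uniform in the box-spacing range.
#' Geometry constraints are asserted on the realized draw.
#'
#' @param config a [sim_config()].
#' @param grid the raw-code [land_grid()] from [generate_landscape()].
#' @return data frame `box_id`, `site_id`, `species`, `x`, `y`.
#' @export
place_sites <- function(config, grid) {
  stopifnot(inherits(config, "sim_config"), inherits(grid, "land_grid"))
  set.seed(component_seed(config$seed, 2L))
  merged <- merge_classes(grid)
  ok_class <- match(forest_classes(), merged$classes)
  cc <- grid_cell_centers(merged)
  lo <- config$margin_m
  hi <- config$extent_m - config$margin_m
  cand <- which(matrix(merged$cells %in% ok_class, merged$n_rows) &
                  outer(cc$y >= lo & cc$y <= hi, cc$x >= lo & cc$x <= hi, "&"),
                arr.ind = TRUE)
  if (!nrow(cand)) stop("no forest cells available inside the margin")
  sx <- numeric(0); sy <- numeric(0)
  tries <- 0L
  max_tries <- 500L * config$n_sites
  d2min <- config$min_site_spacing_m^2
  while (length(sx) < config$n_sites && tries < max_tries) {
    tries <- tries + 1L
    i <- cand[sample.int(nrow(cand), 1L), ]
    px <- cc$x[i[2]] + stats::runif(1, -0.5, 0.5) * config$cell_size_m
    py <- cc$y[i[1]] + stats::runif(1, -0.5, 0.5) * config$cell_size_m
    if (length(sx) && any((sx - px)^2 + (sy - py)^2 < d2min)) next
    sx <- c(sx, px); sy <- c(sy, py)
  }
  if (length(sx) < config$n_sites)
    stop("site packing failed: placed ", length(sx), " of ", config$n_sites,
         " sites after ", max_tries, " proposals; enlarge the extent")
  site_id <- sprintf("S%04d", seq_along(sx))
  rows <- list(data.frame(box_id = paste0(site_id, "_B1"), site_id = site_id,
                          species = config$species, x = sx, y = sy,
                          stringsAsFactors = FALSE))
  if (config$boxes_per_site == 2L) {
    ang <- stats::runif(length(sx), 0, 2 * pi)
    dd <- stats::runif(length(sx), config$box_spacing_m[1], config$box_spacing_m[2])
    rows[[2]] <- data.frame(box_id = paste0(site_id, "_B2"), site_id = site_id,
                            species = config$species,
                            x = sx + dd * cos(ang), y = sy + dd * sin(ang),
                            stringsAsFactors = FALSE)
  }
  boxes <- do.call(rbind, rows)
  # assert geometry on every draw
  if (length(sx) > 1L) {
    dmin <- min(stats::dist(cbind(sx, sy)))
    stopifnot(dmin >= config$min_site_spacing_m)
  }
  if (config$boxes_per_site == 2L) {
    sp <- sqrt((rows[[1]]$x - rows[[2]]$x)^2 + (rows[[1]]$y - rows[[2]]$y)^2)
    stopifnot(all(sp >= config$box_spacing_m[1] - 1e-9),
              all(sp <= config$box_spacing_m[2] + 1e-9))
  }
  boxes[order(boxes$box_id), ]
}

#' Simulate predator nest locations across years
#'
#' Year-one nests are a Poisson process at the configured density, thinned
#' to forest cells; in each later year every nest keeps its location with
#' probability `territory_persistence` and otherwise relocates to a fresh
#' forest location. Nests are generated from the year before the first
#' analysis year (so lag-1 covariates are defined) through the last.
#'
#' @param config a [sim_config()].
#' @param grid the raw-code [land_grid()].
#' @return data frame `species`, `year`, `x`, `y`.
#' @export
place_predator_nests <- function(config, grid) {
  stopifnot(inherits(config, "sim_config"), inherits(grid, "land_grid"))
  set.seed(component_seed(config$seed, 3L))
  merged <- merge_classes(grid)
  ok_class <- match(forest_classes(), merged$classes)
  cc <- grid_cell_centers(merged)
  cand <- which(matrix(merged$cells %in% ok_class, merged$n_rows), arr.ind = TRUE)
  draw_points <- function(k) {
    i <- cand[sample.int(nrow(cand), k, replace = TRUE), , drop = FALSE]
    cbind(cc$x[i[, 2]] + stats::runif(k, -0.5, 0.5) * config$cell_size_m,
          cc$y[i[, 1]] + stats::runif(k, -0.5, 0.5) * config$cell_size_m)
  }
  area_km2 <- (config$extent_m / 1000)^2
  years <- (min(config$years) - 1L):max(config$years)
  out <- list()
  for (sp in names(config$predator_density)) {
    lambda <- config$predator_density[[sp]] * area_km2 / 10
    n1 <- stats::rpois(1, lambda)
    pts <- draw_points(max(n1, 0L))
    for (yr in years) {
      if (yr > years[1] && nrow(pts)) {
        move <- stats::runif(nrow(pts)) > config$territory_persistence
        if (any(move)) pts[move, ] <- draw_points(sum(move))
      }
      if (nrow(pts))
        out[[length(out) + 1L]] <- data.frame(species = sp, year = yr,
                                              x = pts[, 1], y = pts[, 2],
                                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# yearly cone index: log-normal baseline with occasional mast years
generate_cone_series <- function(config) {
  if (!is.null(config$cone_series)) return(config$cone_series)
  set.seed(component_seed(config$seed, 4L))
  years <- (min(config$years) - 1L):max(config$years)
  p <- config$cone
  mast <- stats::runif(length(years)) < p$mast_prob
  crop <- ifelse(mast,
                 exp(stats::rnorm(length(years), p$mast_meanlog, p$mast_sdlog)),
                 exp(stats::rnorm(length(years), p$meanlog, p$sdlog)))
  data.frame(year = years, crop = crop)
}

# build the standardized covariate column for one coefficient name
truth_column <- function(term, occ, std_cache) {
  if (term %in% names(std_cache)) return(std_cache[[term]])
  if (grepl("\\^2$", term)) {
    parent <- sub("\\^2$", "", term)
    return(truth_column(parent, occ, std_cache)^2)
  }
  if (grepl(":", term, fixed = TRUE)) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    return(truth_column(parts[1], occ, std_cache) *
             truth_column(parts[2], occ, std_cache))
  }
  if (term == "time_period2") return(as.numeric(occ$year >= 2006))
  if (!term %in% names(occ))
    stop("true coefficient '", term, "' has no matching covariate column")
  as.numeric(standardize(occ[[term]], name = term))
}

#' Simulate a complete nest-box study
#'
#' Runs the full generator chain — landscape, site and box placement,
#' predator territories, cone series — then computes the covariates the
#' analysis pipeline would compute (small-buffer habitat composition and
#' the kernel risk covariate under the configured truth), and draws
#' occupancy from the logistic model
#' `eta = beta0 + sum(beta * x_std) + b_site + b_box`, with independent
#' Gaussian random intercepts. A raw visit table (with repeat visits and a
#' few late-checked box-years) is generated so the cleaning step can be
#' exercised end to end. Fully deterministic given `config$seed`; each
#' component draws from its own derived stream.
#'
#' @param config a [sim_config()].
#' @return list with `config`, `grid` (raw codes), `grid_merged`, `boxes`,
#'   `nests`, `cone`, `occ` (box-year table with outcome and raw
#'   covariates), `visits`, and `truth` (true betas, standardized design,
#'   linear predictor, probabilities and random-intercept draws).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  grid <- generate_landscape(config)
  merged <- merge_classes(grid)
  boxes <- place_sites(config, grid)
  nests <- place_predator_nests(config, grid)
  cone <- generate_cone_series(config)

  hab <- habitat_wide(habitat_composition(merged, boxes, config$buffer_small))
  occ <- expand.grid(box_id = boxes$box_id, year = config$years,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  occ <- merge(occ, boxes[c("box_id", "site_id", "x", "y")], by = "box_id")
  occ <- merge(occ, hab, by = "box_id")
  main <- nests[nests$species == config$main_predator, , drop = FALSE]
  rc <- suppressMessages(risk_covariate(
    boxes, main, config$kernel_truth, config$years, lag = config$kernel_lag,
    aggregation = config$aggregation))
  occ$risk <- rc$value[match(paste(occ$box_id, occ$year),
                             paste(rc$box_id, rc$year))]
  occ$cone <- cone$crop[match(occ$year - 1L, cone$year)]
  occ$time_period <- ifelse(occ$year < 2006, 1L, 2L)
  occ <- occ[order(occ$box_id, occ$year), ]
  rownames(occ) <- NULL

  set.seed(component_seed(config$seed, 5L))
  X <- matrix(1, nrow(occ), length(config$beta),
              dimnames = list(NULL, names(config$beta)))
  for (term in setdiff(names(config$beta), "(Intercept)"))
    X[, term] <- truth_column(term, occ, list())
  eta <- as.numeric(X %*% config$beta)
  sites <- unique(occ$site_id)
  b_site <- stats::rnorm(length(sites), 0, config$sigma_site)
  names(b_site) <- sites
  box_ids <- unique(occ$box_id)
  b_box <- stats::rnorm(length(box_ids), 0, config$sigma_box)
  names(b_box) <- box_ids
  eta <- eta + b_site[occ$site_id] + b_box[occ$box_id]
  p <- stats::plogis(eta)
  occ$occupied <- stats::rbinom(nrow(occ), 1L, p)

  set.seed(component_seed(config$seed, 6L))
  n <- nrow(occ)
  month <- sample(3:6, n, replace = TRUE)
  late <- stats::runif(n) < 0.02
  month[late] <- 7L
  day <- sample(1:28, n, replace = TRUE)
  visits <- data.frame(box_id = occ$box_id,
                       date = sprintf("%d-%02d-%02d", occ$year, month, day),
                       occupied = occ$occupied, stringsAsFactors = FALSE)
  extra <- which(stats::runif(n) < 0.3 & month < 6)
  if (length(extra)) {
    visits <- rbind(visits, data.frame(
      box_id = occ$box_id[extra],
      date = sprintf("%d-%02d-%02d", occ$year[extra], month[extra] + 1L,
                     day[extra]),
      occupied = stats::rbinom(length(extra), 1L, 0.5),
      stringsAsFactors = FALSE))
  }
  visits <- visits[order(visits$box_id, visits$date), ]
  rownames(visits) <- NULL

  list(config = config, grid = grid, grid_merged = merged, boxes = boxes,
       nests = nests, cone = cone, occ = occ, visits = visits,
       truth = list(beta = config$beta, design = X, eta = eta,
                    probability = p, b_site = b_site, b_box = b_box,
                    late_checked = occ$box_id[late]))
}

#' Write a simulated study to plain-text fixture files
#'
#' Writes `grid.asc` (raw-code ESRI ASCII), `boxes.csv`, `visits.csv`,
#' `predators.csv`, `cones.csv` and `truth.json` into a directory, the
#' input layout [run_pipeline()] consumes.
#'
#' @param sim output of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_grid(sim$grid, file.path(dir, "grid.asc"))
  utils::write.csv(sim$boxes, file.path(dir, "boxes.csv"), row.names = FALSE)
  utils::write.csv(sim$visits, file.path(dir, "visits.csv"), row.names = FALSE)
  utils::write.csv(sim$nests, file.path(dir, "predators.csv"), row.names = FALSE)
  utils::write.csv(sim$cone, file.path(dir, "cones.csv"), row.names = FALSE)
  truth <- list(beta = as.list(sim$truth$beta),
                sigma_site = sim$config$sigma_site,
                sigma_box = sim$config$sigma_box,
                kernel_sd_m = sim$config$kernel_truth$sd_m,
                kernel_flat_top_m = sim$config$kernel_truth$flat_top_m,
                kernel_lag = sim$config$kernel_lag,
                seed = sim$config$seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
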