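# join-count clustering statistic: share of horizontally/vertically adjacent
# cell pairs carrying the same class
same_neighbour_share <- function(grid) {
  m <- grid$cells
  h <- mean(m[, -1] == m[, -ncol(m)])
  v <- mean(m[-1, ] == m[-nrow(m), ])
  (h + v) / 2
}

test_that("the generator is byte-identical under a fixed seed", {
  cfg <- sim_config("flying", seed = 101, n_sites = 30, years = 2002:2004,
                    margin_m = 300, class_mix = coarse_mix())
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$grid$cells, s2$grid$cells)
  expect_identical(s1$boxes, s2$boxes)
  expect_identical(s1$nests, s2$nests)
  expect_identical(s1$occ, s2$occ)
  expect_identical(s1$visits, s2$visits)
  # a different seed changes the draw
  s3 <- simulate_study(sim_config("flying", seed = 102, n_sites = 30,
                                  years = 2002:2004, margin_m = 300,
                                  class_mix = coarse_mix()))
  expect_false(identical(s1$occ$occupied, s3$occ$occupied))
})

test_that("landscapes hit the target class mix and cluster at the set range", {
  cfg <- sim_config("flying", seed = 55, n_sites = 10, extent_m = 10000,
                    margin_m = 200, cell_size_m = 50)
  g <- generate_landscape(cfg)
  shares <- table(factor(g$cells,
                         levels = riskscape:::raw_code_of(names(cfg$class_mix)))) /
    length(g$cells)
  expect_true(all(abs(as.numeric(shares) - cfg$class_mix) < 0.03))
  # single-class mix: uniform grid
  uni <- sim_config("flying", seed = 55, n_sites = 10, extent_m = 4000,
                    margin_m = 200, class_mix = c("Mo spruce" = 1))
  expect_equal(unique(as.vector(generate_landscape(uni)$cells)), 11L)
  # clustering increases the same-class neighbour share
  base <- list(species = "flying", seed = 56, n_sites = 10, extent_m = 5000,
               margin_m = 200, class_mix = coarse_mix(), cell_size_m = 25)
  g0 <- generate_landscape(do.call(sim_config, c(base, clustering_range_m = 0)))
  g2 <- generate_landscape(do.call(sim_config, c(base, clustering_range_m = 2000)))
  expect_gt(same_neighbour_share(g2), same_neighbour_share(g0))
})

test_that("site and box geometry respects the study spacing constraints", {
  sim <- small_flying_sim(57, n_sites = 40)
  b1 <- sim$boxes[grepl("_B1$", sim$boxes$box_id), ]
  b2 <- sim$boxes[grepl("_B2$", sim$boxes$box_id), ]
  expect_gte(min(dist(cbind(b1$x, b1$y))), 800)
  spacing <- sqrt((b1$x - b2$x)^2 + (b1$y - b2$y)^2)
  expect_true(all(spacing >= 80 & spacing <= 100))
  expect_false(anyDuplicated(sim$boxes$box_id) > 0)
  # red design: one box per site
  red <- simulate_study(sim_config("red", seed = 58, n_sites = 30,
                                   years = 2004:2007, margin_m = 300,
                                   class_mix = coarse_mix()))
  expect_true(all(table(red$boxes$site_id) == 1))
  expect_equal(red$occ$time_period, ifelse(red$occ$year < 2006, 1L, 2L))
})

test_that("predator territories persist or relocate as configured", {
  cfg1 <- sim_config("flying", seed = 59, n_sites = 20, years = 2002:2006,
                     margin_m = 300, class_mix = coarse_mix(),
                     territory_persistence = 1)
  g <- generate_landscape(cfg1)
  n1 <- place_predator_nests(cfg1, g)
  owl <- n1[n1$species == "ural_owl", ]
  xs <- split(owl$x, owl$year)
  for (k in seq_along(xs)[-1]) expect_equal(xs[[k]], xs[[1]])
  cfg0 <- sim_config("flying", seed = 59, n_sites = 20, years = 2002:2006,
                     margin_m = 300, class_mix = coarse_mix(),
                     territory_persistence = 0)
  n0 <- place_predator_nests(cfg0, g)
  owl0 <- n0[n0$species == "ural_owl", ]
  ys <- split(owl0$x, owl0$year)
  expect_false(isTRUE(all.equal(ys[[1]], ys[[2]])))
  # counts are constant across years (relocation, not death)
  expect_equal(length(unique(table(owl0$year))), 1)
})

test_that("year-one nest counts follow the configured Poisson density", {
  cfg <- sim_config("flying", seed = 60, n_sites = 20, years = 2002:2003,
                    extent_m = 10000, margin_m = 300, class_mix = coarse_mix())
  g <- generate_landscape(cfg)
  expected <- 2 * (10000 / 1000)^2 / 10  # 2 pairs per 10 km^2 on 100 km^2
  counts <- vapply(1:200, function(s) {
    ck <- cfg
    ck$seed <- 60 + s
    n <- place_predator_nests(ck, g)
    sum(n$species == "ural_owl" & n$year == 2001)
  }, numeric(1))
  expect_lt(abs(mean(counts) - expected), 1.0)
})

test_that("occupancy rates follow the logistic closed forms", {
  # all betas zero, no random effects: occupancy 1/2
  cfg <- sim_config("flying", seed = 61, n_sites = 100, years = 2002:2011,
                    margin_m = 300, class_mix = coarse_mix(),
                    beta = c("(Intercept)" = 0), sigma_site = 0, sigma_box = 0)
  sim <- simulate_study(cfg)
  expect_gte(nrow(sim$occ), 2000)
  expect_lt(abs(mean(sim$occ$occupied) - 0.5), 0.02)
  expect_true(all(sim$truth$probability == 0.5))
  # strongly negative intercept: rare occupancy at the analytic rate
  cfg2 <- sim_config("flying", seed = 62, n_sites = 130, years = 2002:2021,
                     margin_m = 300, class_mix = coarse_mix(),
                     beta = c("(Intercept)" = -4), sigma_site = 0, sigma_box = 0)
  sim2 <- simulate_study(cfg2)
  expect_gte(nrow(sim2$occ), 5000)
  expect_lt(abs(mean(sim2$occ$occupied) - plogis(-4)), 0.01)
})

test_that("the simulation truth is sufficient to reconstruct the outcome process", {
  sim <- small_flying_sim(63, n_sites = 40)
  tr <- sim$truth
  expect_equal(plogis(tr$eta), tr$probability, tolerance = 1e-12)
  expect_true(all(tr$probability > 0 & tr$probability < 1))
  # standardized design columns have mean 0, SD 1
  for (term in c("year", "risk", "Field")) {
    expect_equal(mean(tr$design[, term]), 0, tolerance = 1e-8)
    expect_equal(sd(tr$design[, term]), 1, tolerance = 1e-8)
  }
  eta_check <- as.numeric(tr$design %*% tr$beta) +
    tr$b_site[sim$occ$site_id] + tr$b_box[sim$occ$box_id]
  expect_equal(unname(eta_check), unname(tr$eta), tolerance = 1e-12)
  # an unknown coefficient name is a configuration error
  expect_error(simulate_study(sim_config("flying", seed = 63, n_sites = 30,
                                         years = 2002:2003, margin_m = 300,
                                         class_mix = coarse_mix(),
                                         beta = c("(Intercept)" = 0,
                                                  nosuch = 1))),
               "nosuch")
})

test_that("written study fixtures are plain text and round-trip through the readers", {
  sim <- small_flying_sim(64, n_sites = 25, years = 2002:2004)
  dir <- withr::local_tempdir()
  write_study(sim, dir)
  expect_setequal(list.files(dir),
                  c("grid.asc", "boxes.csv", "visits.csv", "predators.csv",
                    "cones.csv", "truth.json"))
  g <- read_grid(file.path(dir, "grid.asc"))
  expect_identical(g$cells, sim$grid$cells)
  boxes <- read.csv(file.path(dir, "boxes.csv"))
  expect_equal(nrow(boxes), nrow(sim$boxes))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$kernel_sd_m, sim$config$kernel_truth$sd_m)
})
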