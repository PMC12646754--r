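test_that("plot tables are reproducible from the seed", {
  cfg <- generator_config(n_plots = 40, seed = 11)
  t1 <- simulate_plot_table(default_truth, cfg)
  t2 <- simulate_plot_table(default_truth, cfg)
  expect_identical(t1, t2)
  t3 <- simulate_plot_table(default_truth, generator_config(n_plots = 40, seed = 12))
  expect_false(identical(t1, t3))
})

test_that("zero noise puts every record exactly on the truth curves", {
  tab <- small_table(seed = 3, n = 50, noise0 = TRUE)
  for (m in truth_metrics()) {
    col <- c(h_max = "h_max_m", cover = "cover_5m_pct", h_cv = "h_cv",
             rumple_norm = "rumple_norm", basal_area = "basal_area_m2ha",
             tree_density = "tree_density_ha")[[m]]
    expect_equal(
      tab[[col]],
      truth_value(default_truth, m, tab$stand_age_yr, tab$rainfall_mm_yr,
                  tab$plot_area_ha),
      tolerance = 1e-12, info = m
    )
  }
})

test_that("sampled plot areas match the target lognormal moments", {
  tab <- simulate_plot_table(default_truth, generator_config(seed = 5))
  expect_lt(abs(mean(tab$plot_area_ha) - 4.4), 0.4)
  expect_lt(abs(sd(tab$plot_area_ha) - 2.0), 0.7)
})

test_that("noise truncation keeps metrics inside their valid ranges", {
  cfg <- generator_config(
    n_plots = 400,
    noise_sd = list(h_max = 30, cover = 80, h_cv = 2, rumple_norm = 2,
                    basal_area = 40, log10_density = 1),
    seed = 9
  )
  tab <- simulate_plot_table(default_truth, cfg)
  expect_true(all(tab$cover_5m_pct >= 0 & tab$cover_5m_pct <= 100))
  expect_true(all(tab$h_max_m >= 0))
  expect_true(all(tab$h_cv >= 0))
  expect_true(all(tab$rumple_norm >= 0))
  expect_true(all(tab$basal_area_m2ha >= 0))
  expect_true(all(tab$tree_density_ha > 0))
})

test_that("age-rainfall dependence honours the configured correlation", {
  # |cor| <= 0.15 at n = 250 is a ~2.4 sigma band: allow one excursion in 10
  cors0 <- vapply(1:10, function(s) {
    tab <- simulate_plot_table(default_truth, generator_config(seed = s))
    cor(tab$stand_age_yr, tab$rainfall_mm_yr)
  }, 0)
  expect_lt(abs(mean(cors0)), 0.05)
  expect_gte(sum(abs(cors0) <= 0.15), 9)
  corsn <- vapply(1:10, function(s) {
    tab <- simulate_plot_table(
      default_truth,
      generator_config(age_rainfall_correlation = -0.57, seed = s)
    )
    cor(tab$stand_age_yr, tab$rainfall_mm_yr)
  }, 0)
  expect_lt(abs(mean(corsn) + 0.57), 0.05)
  expect_gte(sum(abs(corsn + 0.57) <= 0.15), 9)
})

test_that("config validation rejects degenerate settings", {
  expect_error(generator_config(n_plots = 5), class = "firecanopy_bad_argument")
  expect_error(generator_config(age_range = c(100, 100)),
               class = "firecanopy_bad_argument")
  expect_error(generator_config(noise_sd = list(cover = -1)),
               class = "firecanopy_bad_argument")
  expect_error(generator_config(age_rainfall_correlation = 0.3),
               class = "firecanopy_bad_argument")
})

test_that("Boolean intensity matches the coverage formula and its limits", {
  expect_identical(boolean_density_for_cover(0, 17), 0)
  expect_equal(boolean_density_for_cover(0.48, 20), -log(0.52) / 20,
               tolerance = 1e-12)
  expect_equal(boolean_density_for_cover(0.48, 20) * 1e4, 327, tolerance = 0.2)
  expect_equal(boolean_density_for_cover(0.5, 10) /
                 boolean_density_for_cover(0.5, 20), 2, tolerance = 1e-12)
  expect_error(boolean_density_for_cover(1, 20),
               class = "firecanopy_bad_argument")
})

test_that("Boolean intensity delivers the target cover in a disk simulation", {
  # Monte-Carlo check of the coverage formula itself, independent of the
  # stand generator: fixed-radius disks on a torus, pixel-centre coverage
  target <- 0.4
  radius <- 2.5
  area_disk <- pi * radius^2
  lambda <- boolean_density_for_cover(target, area_disk)
  side <- 120
  covered <- vapply(1:8, function(s) {
    set.seed(s)
    n <- rpois(1, lambda * side^2)
    cx <- runif(n, 0, side)
    cy <- runif(n, 0, side)
    px <- rep(seq(0.5, side - 0.5, 2), times = side / 2)
    py <- rep(seq(0.5, side - 0.5, 2), each = side / 2)
    hit <- rep(FALSE, length(px))
    for (i in seq_len(n)) {
      dx <- pmin(abs(px - cx[i]), side - abs(px - cx[i]))
      dy <- pmin(abs(py - cy[i]), side - abs(py - cy[i]))
      hit <- hit | (dx^2 + dy^2 < radius^2)
    }
    mean(hit)
  }, 0)
  expect_lt(abs(mean(covered) - target), 0.03)
})

test_that("stand scenes satisfy their geometric invariants", {
  sc <- simulate_stand_scene(120, area = 1, truth = default_truth, seed = 4)
  expect_true(all(sc$trees$x >= 0 & sc$trees$x <= sc$extent[1]))
  expect_true(all(sc$trees$y >= 0 & sc$trees$y <= sc$extent[2]))
  expect_true(all(sc$trees$height > 0))
  expect_true(all(sc$trees$crown_radius >= 0))
  expect_true(all(sc$trees$crown_radius[sc$trees$is_snag] <= 0.5))
  sc2 <- simulate_stand_scene(120, area = 1, truth = default_truth, seed = 4)
  expect_identical(sc, sc2)
  # old stands are sparser than young ones (density truth is monotone)
  young <- simulate_stand_scene(10, area = 1, truth = default_truth, seed = 7,
                                snags = FALSE)
  old <- simulate_stand_scene(450, area = 1, truth = default_truth, seed = 7,
                              snags = FALSE)
  expect_lt(nrow(old$trees), nrow(young$trees))
})

test_that("a freshly burned scene without snags has no element above 5 m", {
  sc <- simulate_stand_scene(1, area = 0.5, truth = default_truth, seed = 2,
                             snags = FALSE)
  r <- rasterize_scene(sc)
  expect_true(all(r$heights < 5))
  expect_equal(chm_cover(r, 5), 0)
})

test_that("rasterization max-composites crown surfaces over pixel centres", {
  empty <- structure(
    list(trees = tibble::tibble(x = numeric(), y = numeric(),
                                height = numeric(), crown_radius = numeric(),
                                crown_form = character(), is_snag = logical()),
         extent = c(20, 20), age = 1, rainfall = 290, cover_threshold = 5),
    class = "stand_scene"
  )
  expect_true(all(rasterize_scene(empty)$heights == 0))

  cone_scene <- function(trees) {
    structure(list(trees = trees, extent = c(20, 20), age = 1,
                   rainfall = 290, cover_threshold = 5),
              class = "stand_scene")
  }
  # single cone, apex 10 m radius 3 m at a pixel centre (x=10.5, y=10.5)
  tr <- tibble::tibble(x = 10.5, y = 10.5, height = 10, crown_radius = 3,
                       crown_form = "cone", is_snag = FALSE)
  r <- rasterize_scene(cone_scene(tr))
  at <- function(r, x, y) {
    d <- dim(r$heights)
    r$heights[d[1] - floor(y), floor(x) + 1]
  }
  expect_equal(at(r, 10.5, 10.5), 10)
  # pixel centre 3 m away is outside the (open) crown disk
  expect_equal(at(r, 13.5, 10.5), 0)
  expect_equal(at(r, 15.5, 10.5), 0)
  # 1 m away: linear falloff 10 * (1 - 1/3)
  expect_equal(at(r, 11.5, 10.5), 10 * (1 - 1 / 3), tolerance = 1e-12)

  # overlapping crowns: max of the individual surfaces, never the sum
  tr2 <- tibble::tibble(x = c(10.5, 11.5), y = c(10.5, 10.5),
                        height = c(10, 8), crown_radius = c(3, 3),
                        crown_form = "cone", is_snag = FALSE)
  r2 <- rasterize_scene(cone_scene(tr2))
  ra <- rasterize_scene(cone_scene(tr2[1, ]))
  rb <- rasterize_scene(cone_scene(tr2[2, ]))
  expect_equal(r2$heights, pmax(ra$heights, rb$heights))
  expect_lte(max(r2$heights), 10)
})
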