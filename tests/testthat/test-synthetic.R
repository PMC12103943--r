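test_that("zone maps tile the plane on the expected lattice", {
  sc9 <- synthetic_scenario(n_zones = 9, grid_shape = c(10, 10))
  zm <- generate_zone_map(sc9)
  expect_equal(nrow(zm), 9)
  expect_equal(unname(sc9$lattice), c(3L, 3L))
  # full coverage without overlap: total area equals bounding-box area
  area <- sum((zm$xmax - zm$xmin) * (zm$ymax - zm$ymin))
  bbox <- (max(zm$xmax) - min(zm$xmin)) * (max(zm$ymax) - min(zm$ymin))
  expect_equal(area, bbox)
  # pairwise interiors are disjoint
  for (i in 1:8) for (j in (i + 1):9) {
    ox <- min(zm$xmax[i], zm$xmax[j]) - max(zm$xmin[i], zm$xmin[j])
    oy <- min(zm$ymax[i], zm$ymax[j]) - max(zm$ymin[i], zm$ymin[j])
    expect_false(ox > 1e-9 && oy > 1e-9)
  }
  # 88 zones factor into 8 x 11
  sc88 <- synthetic_scenario(n_zones = 88, grid_shape = c(5, 5))
  expect_equal(unname(sc88$lattice), c(8L, 11L))
  expect_error(synthetic_scenario(n_zones = 13, grid_shape = c(5, 5)),
               "lattice")
})

test_that("queen contiguity of zone rectangles equals lattice adjacency", {
  sc <- synthetic_scenario(n_zones = 12, grid_shape = c(6, 6), seed = 2)
  zm <- generate_zone_map(sc)
  w <- queen_weights(zm)
  # analytic lattice adjacency: |drow| <= 1 and |dcol| <= 1, not identical
  for (i in seq_len(nrow(zm))) for (j in seq_len(nrow(zm))) {
    expected <- i != j && abs(zm$zrow[i] - zm$zrow[j]) <= 1 &&
      abs(zm$zcol[i] - zm$zcol[j]) <= 1
    expect_equal(w$B[i, j] == 1, expected)
  }
})

test_that("land-use panel respects persistence, composition and determinism", {
  static <- c(construction = 0.1, arable = 0.2, grassland = 0.2,
              forest = 0.35, water = 0.05, unused = 0.1)
  sc <- synthetic_scenario(n_zones = 9, grid_shape = c(20, 20),
                           class_props = static, persistence = 1, seed = 4)
  panel <- generate_landuse_panel(sc)
  # persistence 1 + static composition: every epoch identical per zone
  for (z in 1:9) {
    yrs <- paste0(z, ":", sc$years)
    for (y in yrs[-1])
      expect_identical(panel[[y]]$values, panel[[yrs[1]]]$values)
  }
  # degenerate proportions give a single-class raster
  mono <- c(construction = 1, arable = 0, grassland = 0,
            forest = 0, water = 0, unused = 0)
  scm <- synthetic_scenario(n_zones = 9, grid_shape = c(15, 15),
                            class_props = mono, seed = 4)
  r1 <- generate_landuse_panel(scm)[["1:2000"]]
  expect_equal(unique(as.vector(r1$values)), 1L)
  # same seed, same panel
  p2 <- generate_landuse_panel(sc)
  expect_identical(panel[["5:2010"]]$values, p2[["5:2010"]]$values)
})

test_that("realized class proportions match targets and improve with grid size", {
  static <- c(construction = 0.1, arable = 0.25, grassland = 0.2,
              forest = 0.3, water = 0.05, unused = 0.1)
  err_at <- function(n) {
    sc <- synthetic_scenario(n_zones = 9, grid_shape = c(n, n),
                             years = 2000L, class_props = static, seed = 8)
    r <- generate_landuse_panel(sc)[["1:2000"]]
    pr <- class_proportions(r)
    got <- setNames(rep(0, 6), as.character(1:6))
    got[as.character(pr$class_code)] <- pr$proportion
    max(abs(got - unname(static)))
  }
  e50 <- err_at(50); e200 <- err_at(200)
  expect_lt(e200, 0.02)       # within 2 percentage points on 200 x 200
  expect_lte(e200, e50 + 1e-9)  # error shrinks with grid size
})

test_that("driver panel carries a sealed truth and recovers exactly when noiseless", {
  flat <- function(value) { force(value); function(u, v, t) rep(value, length(u)) }
  sc <- synthetic_scenario(
    n_zones = 12, grid_shape = c(5, 5), noise_sd = 0, seed = 3,
    coef_surfaces = c(list(intercept = flat(0.3)),
                      lapply(stats::setNames(seq_along(default_driver_fields()),
                                             names(default_driver_fields())),
                             function(i) flat(0.1 * i))))
  dp <- generate_driver_panel(sc)
  drivers <- names(sc$drivers)
  # observable panel holds only ids, coordinates, drivers and the response
  expect_setequal(names(dp$panel),
                  c("zone_id", "year", "t", "u", "v", drivers, "response"))
  # noiseless constant-coefficient data: OLS recovers to machine precision
  ols <- stats::lm(stats::reformulate(drivers, "response"), data = dp$panel)
  expect_equal(unname(coef(ols)), c(0.3, 0.1 * seq_along(drivers)),
               tolerance = 1e-10)
  # determinism
  dp2 <- generate_driver_panel(sc)
  expect_identical(dp$panel, dp2$panel)
})

test_that("response-driver covariance tracks the true coefficient surface", {
  # Monte-Carlo oracle: across replicate panels (same design, fresh noise and
  # driver draws), cov(response, x_pre)/var(x_pre) per observation estimates
  # beta_pre(u, v, t), because driver draws are independent across drivers.
  nrep <- 200
  panels <- lapply(seq_len(nrep), function(r)
    generate_driver_panel(synthetic_scenario(n_zones = 9, grid_shape = c(5, 5),
                                             seed = 1000 + r)))
  truth <- panels[[1]]$truth[, "pre"]
  ys <- sapply(panels, function(d) d$panel$response)
  xs <- sapply(panels, function(d) d$panel$pre)
  est <- vapply(seq_along(truth), function(i)
    stats::cov(ys[i, ], xs[i, ]) / stats::var(xs[i, ]), numeric(1))
  expect_gt(stats::cor(est, truth), 0.9)
  # and the surface direction is recovered: higher u, larger coefficient
  u <- panels[[1]]$panel$u
  expect_gt(mean(est[u > 0.5]), mean(est[u < 0.5]))
})
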