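test_that("VIF screening flags collinear drivers and matches the matrix oracle", {
  set.seed(13)
  n <- 120
  # orthogonal design: nothing removed, VIFs near 1
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  vs <- vif_screen(X, c("a", "b", "c"), threshold = 7.5)
  expect_equal(vs$retained, c("a", "b", "c"))
  expect_true(all(vs$vif < 1.2))
  expect_equal(unname(vs$vif), unname(oracle_vif(as.matrix(X))[vs$retained]),
               tolerance = 1e-8)
  # a duplicated column has infinite VIF and is removed first
  X$dup <- X$a
  vs2 <- vif_screen(X, c("a", "b", "c", "dup"))
  expect_equal(length(vs2$removed), 1)
  expect_true(vs2$removed %in% c("a", "dup"))
  # three drivers with pairwise correlation ~0.95: at least one removed
  z <- rnorm(n)
  C <- data.frame(x1 = z + rnorm(n, 0, 0.22), x2 = z + rnorm(n, 0, 0.22),
                  x3 = z + rnorm(n, 0, 0.22), ortho = rnorm(n))
  vs3 <- vif_screen(C, names(C), threshold = 7.5)
  expect_gte(length(vs3$removed), 1)
  expect_true("ortho" %in% vs3$retained)
  expect_equal(unname(vs3$steps[[1]]),
               unname(oracle_vif(as.matrix(C))), tolerance = 1e-8)
})

test_that("spatiotemporal kernel weights behave at their limits", {
  u <- c(0, 1, 0); v <- c(0, 0, 2); t <- c(0, 5, 10)
  # tau = 0 ignores time entirely
  w0 <- st_weights(0, 0, 0, u, v, t, h = 1, tau = 0)
  expect_equal(w0, exp(-c(0, 1, 4)))
  # hand evaluation with time in play
  w1 <- st_weights(0, 0, 0, u, v, t, h = 2, tau = 0.1)
  expect_equal(w1, exp(-(c(0, 1, 4) + 0.1 * c(0, 25, 100)) / 4))
  # h -> infinity: all weights -> 1; own weight always 1
  expect_equal(st_weights(0, 0, 0, u, v, t, h = 1e9, tau = 1), c(1, 1, 1),
               tolerance = 1e-9)
  expect_equal(w1[1], 1)
  expect_error(st_weights(0, 0, 0, c(NA, 1), c(0, 0), c(0, 0), h = 1),
               "non-finite")
  expect_error(st_weights(0, 0, 0, u, v, t, h = 0), "positive")
})

make_gtwr_panel <- function(n = 80, seed = 17, noise = 0.1,
                            beta1 = function(u, v, t) 1 + 2 * u) {
  set.seed(seed)
  u <- runif(n); v <- runif(n); t <- rep(0:4, length.out = n) * 5
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- 0.5 + beta1(u, v, t) * x1 - 0.8 * x2 + rnorm(n, 0, noise)
  data.frame(u = u, v = v, t = t, x1 = x1, x2 = x2, response = y)
}

test_that("GTWR collapses to OLS at large bandwidth and is exact when noiseless", {
  p <- make_gtwr_panel(noise = 0.1)
  fit <- fit_gtwr(p, "response", c("x1", "x2"), h = 1e6, tau = 0)
  ols <- coef(stats::lm(response ~ x1 + x2, data = p))
  for (i in c(1, 40, 80))
    expect_equal(unname(fit$coefficients[i, ]), unname(ols),
                 tolerance = 1e-6)
  # constant-coefficient noiseless data: exact recovery at any bandwidth
  p0 <- make_gtwr_panel(noise = 0, beta1 = function(u, v, t) rep(1.5, length(u)))
  f0 <- fit_gtwr(p0, "response", c("x1", "x2"), h = 0.3, tau = 0.01)
  expect_equal(unname(colMeans(f0$coefficients)), c(0.5, 1.5, -0.8),
               tolerance = 1e-8)
  expect_equal(max(abs(f0$residuals)), 0, tolerance = 1e-10)
  expect_equal(f0$fitted + f0$residuals, p0$response)
})

test_that("GTWR with tau = 0 on one epoch reproduces plain GWR", {
  p <- make_gtwr_panel(n = 60)
  p$t <- 0
  fit <- fit_gtwr(p, "response", c("x1", "x2"), h = 0.4, tau = 0)
  X <- cbind(1, p$x1, p$x2)
  want <- oracle_gwr(X, p$response, p$u, p$v, h = 0.4)
  expect_equal(unname(fit$coefficients), unname(want), tolerance = 1e-10)
})

test_that("local weighted residuals are orthogonal to the weighted design", {
  p <- make_gtwr_panel(n = 60)
  fit <- fit_gtwr(p, "response", c("x1", "x2"), h = 0.5, tau = 0.02)
  X <- cbind(1, p$x1, p$x2)
  for (i in c(3, 30, 57)) {
    w <- st_weights(p$u[i], p$v[i], p$t[i], p$u, p$v, p$t, h = 0.5, tau = 0.02)
    r_local <- p$response - X %*% fit$coefficients[i, ]
    expect_lt(max(abs(crossprod(X * w, r_local))), 1e-8)
  }
})

test_that("bandwidth selection satisfies the optimizer contract", {
  p <- make_gtwr_panel(n = 80, noise = 0.2)
  bw <- suppressWarnings(
    select_bandwidth(p, "response", c("x1", "x2"), tau_grid = 0))
  crit <- function(h) {
    f <- fit_gtwr(p, "response", c("x1", "x2"), h = h, tau = 0)
    f$aicc
  }
  got <- crit(bw$h)
  set.seed(19)
  for (h in exp(runif(10, log(0.08), log(2.5))))
    expect_lte(got, crit(h) + 1e-8)
})

test_that("stronger coefficient variation selects a smaller bandwidth", {
  pv <- make_gtwr_panel(n = 80, seed = 23, noise = 0.1,
                        beta1 = function(u, v, t) 1 + 4 * u)
  pc <- make_gtwr_panel(n = 80, seed = 23, noise = 0.1,
                        beta1 = function(u, v, t) rep(3, length(u)))
  bv <- suppressWarnings(select_bandwidth(pv, "response", c("x1", "x2"),
                                          tau_grid = 0))
  bc <- suppressWarnings(select_bandwidth(pc, "response", c("x1", "x2"),
                                          tau_grid = 0))
  expect_lt(bv$h, bc$h)
})

test_that("coefficient maps are binned by quantiles with signs reported", {
  lv <- classify_coefficients(matrix(1:8, ncol = 1,
                                     dimnames = list(NULL, "d")), k = 4)
  expect_equal(as.vector(table(lv$level)), c(2, 2, 2, 2))
  expect_warning(classify_coefficients(
    matrix(rep(2, 6), ncol = 1, dimnames = list(NULL, "d")), k = 4),
    "fewer distinct")
  set.seed(29)
  x <- rnorm(40)
  lv2 <- classify_coefficients(matrix(x, ncol = 1,
                                      dimnames = list(NULL, "d")), k = 4)
  qs <- stats::quantile(x, c(0.25, 0.5, 0.75))
  expect_equal(as.character(lv2$level[x < qs[1]]),
               rep("L1", sum(x < qs[1])))
  expect_equal(as.character(lv2$level[x > qs[3]]),
               rep("L4", sum(x > qs[3])))
  expect_equal(lv2$sign, ifelse(x >= 0, "positive", "negative"))
})
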