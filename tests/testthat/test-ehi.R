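make_panel <- function(n = 12, seed = 1) {
  set.seed(seed)
  data.frame(zone_id = rep(1:(n / 2), 2), year = rep(c(2000, 2020), each = n / 2),
             pop = runif(n, 10, 100), ndvi = runif(n), shdi = runif(n, 0, 1.7),
             shei = runif(n), cohesion = runif(n, 80, 100),
             esv = runif(n, 1e5, 9e5), contag = runif(n, 20, 70),
             frac_mn = runif(n, 1, 1.3))
}

test_that("min-max normalization honors indicator orientation", {
  p <- data.frame(a = c(10, 20, 30), b = c(10, 20, 30))
  Y <- normalize_indicators(p, c("a", "b"),
                            orientation = c(a = "positive", b = "negative"))
  expect_equal(Y[, "a"], c(0, 0.5, 1))
  expect_equal(Y[, "b"], c(1, 0.5, 0))   # negative: (max - x)/(max - min)
  expect_warning(
    Yc <- normalize_indicators(data.frame(a = c(1, 1, 1), b = 1:3),
                               c("a", "b"),
                               orientation = c(a = "positive", b = "positive")),
    "constant")
  expect_equal(Yc[, "a"], c(0, 0, 0))
})

test_that("entropy weights reward dispersion and always sum to 1", {
  Y <- cbind(a = c(1, 0, 1), b = c(0, 1, 1))
  w <- entropy_weights(Y)
  expect_equal(unname(w$weights), c(0.5, 0.5))   # symmetric columns
  expect_equal(w$k, 1 / log(3))
  expect_equal(unname(w$d), unname(1 - w$entropy))
  # perturbing one entry shifts weight toward the more dispersed column
  Y2 <- Y; Y2[3, 2] <- 0.5
  w2 <- entropy_weights(Y2)$weights
  expect_equal(unname(w2), c(0.4673609, 0.5326391), tolerance = 1e-6)
  expect_gt(w2["b"], w2["a"])
  # identical columns get equal weights; weights sum to 1 on random input
  set.seed(2)
  for (r in 1:20) {
    M <- matrix(runif(40), 10, 4)
    M[, 4] <- M[, 1]
    ww <- entropy_weights(M)$weights
    expect_equal(sum(ww), 1)
    expect_equal(ww[[1]], ww[[4]])
  }
  expect_error(entropy_weights(Y[1, , drop = FALSE]), "at least 2")
  # an all-zero column carries no information
  expect_equal(entropy_weights(cbind(a = c(0, 0, 0), b = c(0, 1, 1)))$weights[["a"]], 0)
})

test_that("the composite index is the weighted sum and respects its bounds", {
  expect_equal(compute_ehi(matrix(c(0.4, 0.8), 1), c(0.25, 0.75)), 0.7)
  expect_equal(compute_ehi(matrix(1, 2, 3), rep(1 / 3, 3)), c(1, 1))
  expect_equal(compute_ehi(matrix(0, 2, 3), rep(1 / 3, 3)), c(0, 0))
  expect_error(compute_ehi(matrix(1, 2, 3), c(0.5, 0.5)), "ncol")
})

test_that("EHI grades and change levels reproduce the printed bands", {
  expect_equal(as.character(classify_ehi(c(0.45, 0.57, 0.70))),
               c("I", "III", "IV"))
  expect_equal(as.character(classify_ehi(0.5)), "II")  # boundary goes upward
  sweep <- classify_ehi(seq(0, 1, length.out = 10001))
  expect_equal(sort(unique(as.character(sweep))), c("I", "II", "III", "IV"))
  expect_false(anyNA(sweep))
  expect_error(classify_ehi(1.2), "\\[0, 1\\]")

  expect_equal(as.character(classify_delta(c(0.09, 0.05, 0.12, 0.065))),
               c("II", "out-of-range", "III", "I"))
})

test_that("scoring is monotone and scale invariant", {
  p <- make_panel()
  res <- ehi_assess(p)
  expect_equal(sum(res$weights$weights), 1)
  # monotonicity: raising a positive indicator of one observation (weights
  # fixed) never lowers its EHI
  Y <- res$normalized
  w <- res$weights$weights
  Y2 <- Y; Y2[3, "ndvi"] <- min(1, Y2[3, "ndvi"] + 0.2)
  expect_gte(compute_ehi(Y2, w)[3], compute_ehi(Y, w)[3])
  # scale invariance: rescaling a raw column changes nothing downstream
  p2 <- p; p2$esv <- p2$esv * 1000
  res2 <- ehi_assess(p2)
  expect_equal(res2$normalized, res$normalized)
  expect_equal(res2$weights$weights, res$weights$weights)
  expect_equal(res2$scores$ehi, res$scores$ehi)
  # criterion-layer weights are the sums of their members
  cw <- res$criterion_weights
  ww <- res$weights$weights
  expect_equal(unname(cw["pressure"]), unname(ww["pop"]))
  expect_equal(unname(cw["state"]),
               unname(sum(ww[c("ndvi", "shdi", "shei", "cohesion")])))
  expect_equal(unname(cw["response"]),
               unname(sum(ww[c("esv", "contag", "frac_mn")])))
})

test_that("delta classification uses first and last years per zone", {
  p <- make_panel()
  res <- ehi_assess(p)
  s <- res$scores
  z1 <- s$ehi[s$year == 2020][1] - s$ehi[s$year == 2000][1]
  expect_equal(res$delta$delta_ehi[1], z1)
  expect_equal(nrow(res$delta), 6)
})
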