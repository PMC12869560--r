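test_that("marginal KDE grid recovers uniform interval masses", {
  set.seed(1)
  x <- stats::runif(100000, 0, 5)
  g <- fit_marginal_kde(x, grid_resolution = 1, variable = "u")
  core <- which(g$grid[-length(g$grid)] >= 0 & g$grid[-1] <= 5)
  expect_equal(sum(g$masses["(pooled)", ]), 1, tolerance = 1e-9)
  interior <- core[-c(1, length(core))]
  expect_true(all(abs(g$masses["(pooled)", interior] - 0.2) < 0.01))
  # Gaussian-kernel boundary bias leaks a little mass past the edges
  expect_true(all(abs(g$masses["(pooled)", core] - 0.2) < 0.03))
})

test_that("an exact uniform CDF differenced on the grid gives exact masses", {
  grid <- 0:5
  masses <- diff(stats::punif(grid, 0, 5))
  expect_equal(masses, rep(0.2, 5))
})

test_that("small strata fall back to the pooled grid and are flagged", {
  set.seed(2)
  x <- c(stats::rnorm(500, 10), stats::rnorm(3, 30))
  lab <- c(rep("big", 500), rep("tiny", 3))
  g <- fit_marginal_kde(x, lab, grid_resolution = 1, min_stratum_n = 30)
  expect_true("tiny" %in% g$fallback_strata)
  expect_equal(g$masses["tiny", ], g$masses["(pooled)", ])
  expect_false("big" %in% g$fallback_strata)
})

test_that("constant input is handled as a point mass", {
  g <- fit_marginal_kde(rep(7, 100), grid_resolution = 1)
  expect_true(g$degenerate)
  v <- sample_within_band(c(0, 20), g, n = 200)
  expect_true(all(v >= 7 & v <= 8.0001))
})

test_that("two-stage sampling stays inside the band and follows the masses", {
  set.seed(3)
  # skewed distribution: most mass near zero
  x <- stats::rexp(50000, rate = 0.5)
  g <- fit_marginal_kde(x, grid_resolution = 1, variable = "skew")
  band <- c(0, 5)
  v <- sample_within_band(band, g, n = 50000)
  expect_true(all(v >= 0 & v < 5))
  # chi-square of subinterval counts against grid masses
  gl <- g$grid[-length(g$grid)]; gh <- g$grid[-1]
  inside <- which(gl >= band[1] & gh <= band[2])
  m <- g$masses["(pooled)", inside]
  cnt <- tabulate(findInterval(v, g$grid), nbins = length(gl))[inside]
  keep <- m > 1e-6
  p <- suppressWarnings(stats::chisq.test(cnt[keep],
                                          p = m[keep] / sum(m[keep]))$p.value)
  expect_gt(p, 0.01)
  # degenerate first subinterval: all mass in one cell
  g2 <- g
  g2$masses["(pooled)", ] <- 0
  g2$masses["(pooled)", inside[1]] <- 1
  v2 <- sample_within_band(c(gl[inside[1]], gh[inside[1]] + 3), g2, n = 500)
  expect_true(all(v2 >= gl[inside[1]] & v2 < gh[inside[1]]))
})

test_that("zero-mass bands fall back to uniform draws with a flag", {
  set.seed(4)
  x <- stats::rnorm(1000, 5, 0.5)
  g <- fit_marginal_kde(x, grid_resolution = 0.5)
  v <- sample_within_band(c(100, 110), g, n = 300)
  expect_equal(attr(v, "n_fallback"), 300)
  expect_true(all(v >= 100 & v < 110))
})

test_that("inclusion-exclusion rectangle masses match closed forms", {
  # product CDF F(x, y) = x * y on the unit square
  gx <- seq(0, 1, 0.1)
  joint <- list(grid_x = gx, grid_y = gx, cdf = outer(gx, gx))
  expect_equal(joint_interval_mass(joint, c(0.2, 0.4), c(0.1, 0.3)), 0.04,
               tolerance = 1e-12)
  # comonotone CDF F(x, y) = min(x, y): the off-diagonal block is empty
  joint2 <- list(grid_x = gx, grid_y = gx, cdf = outer(gx, gx, pmin))
  expect_equal(joint_interval_mass(joint2, c(0, 0.5), c(0.5, 1)), 0)
  expect_error(joint_interval_mass(joint, c(0.25, 0.4), c(0.1, 0.3)),
               "not on the grid")
})

test_that("joint cell masses marginalise exactly to the 1-D masses", {
  set.seed(5)
  x <- stats::rnorm(2000, 10, 2)
  y <- 0.5 * x + stats::rnorm(2000, 0, 1)
  j <- fit_joint_kde(x, y, 0.5, 0.5)
  expect_equal(rowSums(j$cell_mass), j$marginal_x, tolerance = 1e-12)
  expect_equal(colSums(j$cell_mass), j$marginal_y, tolerance = 1e-12)
  expect_equal(sum(j$cell_mass), 1, tolerance = 1e-9)
  # telescoping: summing rectangle masses over all y-intervals for a fixed
  # x-interval reproduces the marginal x-interval mass
  gx <- j$grid_x; gy <- j$grid_y
  i <- 5
  per_y <- vapply(seq_len(length(gy) - 1), function(k)
    joint_interval_mass(j, gx[c(i, i + 1)], gy[c(k, k + 1)]), numeric(1))
  direct <- j$cdf[i + 1, length(gy)] - j$cdf[i, length(gy)] -
    j$cdf[i + 1, 1] + j$cdf[i, 1]
  expect_equal(sum(per_y), direct, tolerance = 1e-9)
})

test_that("joint sampling preserves independence and dependence", {
  set.seed(6)
  # independent pair: sampled correlation near zero
  x <- stats::runif(20000, 0, 10)
  y <- stats::runif(20000, 0, 10)
  j <- fit_joint_kde(x, y, 0.5, 0.5)
  s <- sample_joint_within_bands(c(0, 10), c(0, 10), j, n = 50000)
  expect_lt(abs(stats::cor(s$x, s$y)), 0.02)
  # strongly dependent pair: correlation survives band-restricted sampling
  x2 <- stats::rnorm(20000, 10, 2)
  y2 <- x2 + stats::rnorm(20000, 0, 0.8)
  j2 <- fit_joint_kde(x2, y2, 0.5, 0.5)
  s2 <- sample_joint_within_bands(range(j2$grid_x), range(j2$grid_y), j2,
                                  n = 50000)
  expect_gt(stats::cor(s2$x, s2$y), 0.5)
  # a single nonzero cell makes the draw deterministic at cell level
  j3 <- j2
  j3$cell_mass <- j3$cell_mass * 0
  j3$cell_mass[4, 6] <- 1
  s3 <- sample_joint_within_bands(range(j3$grid_x), range(j3$grid_y), j3,
                                  n = 100)
  expect_true(all(s3$x >= j3$grid_x[4] & s3$x <= j3$grid_x[5]))
  expect_true(all(s3$y >= j3$grid_y[6] & s3$y <= j3$grid_y[7]))
  # zero-mass rectangle: independent marginal fallback, flagged
  s4 <- sample_joint_within_bands(c(-1000, -990), c(-1000, -990), j2, n = 10)
  expect_equal(attr(s4, "n_fallback"), 10)
})
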