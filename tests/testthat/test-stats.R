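test_that("spearman matrix recovers monotone relations and the oracle", {
  x <- c(0.5, 1, 2, 3.5, 7)
  tab <- data.frame(x = x, sq = x^2, neg = -x)
  res <- spearman_matrix(tab)
  expect_equal(res$rho[res$var_x == "x" & res$var_y == "sq"], 1)
  expect_equal(res$rho[res$var_x == "x" & res$var_y == "neg"], -1)
  # random table with ties against the explicit-sum oracle
  set.seed(61)
  tab2 <- data.frame(a = rpois(6, 3), b = rnorm(6), c = runif(6),
                     d = rpois(6, 2), e = rnorm(6))
  res2 <- spearman_matrix(tab2)
  for (k in seq_len(nrow(res2))) {
    expect_equal(res2$rho[k],
                 bf_spearman(tab2[[res2$var_x[k]]], tab2[[res2$var_y[k]]]),
                 tolerance = 1e-12)
  }
  # Bonferroni family = all pairs
  expect_equal(res2$p_adj, pmin(1, res2$p_raw * nrow(res2)))
})

test_that("spearman matrix is symmetric and monotone-invariant", {
  set.seed(62)
  tab <- data.frame(a = rnorm(20), b = rexp(20), c = runif(20))
  r1 <- spearman_matrix(tab)
  tab2 <- data.frame(a = exp(tab$a), b = tab$b^3, c = qlogis(tab$c))
  r2 <- spearman_matrix(tab2)
  expect_equal(r1$rho, r2$rho, tolerance = 1e-12)
  expect_warning(spearman_matrix(data.frame(a = 1:5, k = rep(1, 5))),
                 "constant")
})

test_that("partial spearman matches the precision-matrix oracle", {
  set.seed(63)
  for (rep in 1:5) {
    tab <- data.frame(x = rnorm(8), y = rnorm(8), c1 = rnorm(8),
                      c2 = rnorm(8))
    p1 <- partial_spearman(tab, "x", "y", "c1")
    expect_equal(p1$rho, bf_partial_spearman(tab, "x", "y", "c1"),
                 tolerance = 1e-10)
    p2 <- partial_spearman(tab, "x", "y", c("c1", "c2"))
    expect_equal(p2$rho, bf_partial_spearman(tab, "x", "y", c("c1", "c2")),
                 tolerance = 1e-10)
  }
})

test_that("partial spearman with one control follows the recursion formula", {
  set.seed(64)
  tab <- data.frame(x = rnorm(40), y = rnorm(40), z = rnorm(40))
  rxy <- bf_spearman(tab$x, tab$y)
  rxz <- bf_spearman(tab$x, tab$z)
  ryz <- bf_spearman(tab$y, tab$z)
  expected <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  got <- partial_spearman(tab, "x", "y", "z")$rho
  expect_equal(got, expected, tolerance = 1e-10)
  # empty controls reduce to plain Spearman exactly
  expect_equal(partial_spearman(tab, "x", "y")$rho, rxy,
               tolerance = 1e-12)
})

test_that("partial spearman isolates and removes control effects", {
  set.seed(65)
  n <- 500
  c0 <- rnorm(n)
  # y = x with an irrelevant control: partial stays ~1
  x <- rnorm(n)
  tab <- data.frame(x = x, y = x, c0 = c0)
  expect_gte(partial_spearman(tab, "x", "y", "c0")$rho, 0.99)
  # y = control, x independent: partial ~0
  tab2 <- data.frame(x = rnorm(n), y = c0, c0 = c0)
  expect_lt(abs(partial_spearman(tab2, "x", "y", "c0")$rho), 0.1)
})

test_that("varpart2 matches lm-based and vegan oracles and sums to one", {
  set.seed(66)
  n <- 60
  X1 <- matrix(rnorm(n), ncol = 1)
  X2 <- matrix(rnorm(n * 4), ncol = 4)
  y <- 0.8 * X1[, 1] + 0.5 * X2[, 1] + rnorm(n, 0, 0.5)
  vp <- varpart2(y, X1, X2)
  expect_equal(vp$frac_a + vp$frac_b + vp$frac_c + vp$frac_d, 1,
               tolerance = 1e-9)
  bf <- bf_varpart(y, X1, X2)
  expect_equal(vp$frac_a, unname(bf["frac_a"]), tolerance = 1e-10)
  expect_equal(vp$frac_b, unname(bf["frac_b"]), tolerance = 1e-10)
  expect_equal(vp$frac_c, unname(bf["frac_c"]), tolerance = 1e-10)
  expect_equal(vp$frac_d, unname(bf["frac_d"]), tolerance = 1e-10)
  skip_if_not_installed("vegan")
  # vegan indfract rows: unique X1, unique X2, shared, residual
  vv <- vegan::varpart(y, X1, X2)$part$indfract$Adj.R.square
  expect_equal(vp$frac_a, vv[1], tolerance = 1e-8)
  expect_equal(vp$frac_c, vv[2], tolerance = 1e-8)
  expect_equal(vp$frac_b, vv[3], tolerance = 1e-8)
  expect_equal(vp$frac_d, vv[4], tolerance = 1e-8)
})

test_that("varpart2 saturation and noise limits behave", {
  set.seed(67)
  n <- 200
  X1 <- matrix(rnorm(n), ncol = 1)
  X2 <- matrix(rnorm(n * 4), ncol = 4)
  vp <- varpart2(X1[, 1] * 2, X1, X2)     # y exactly X1
  expect_gt(vp$frac_a, 0.97)
  expect_lt(abs(vp$frac_c), 0.03)
  expect_lt(abs(vp$frac_d), 0.03)
  vp2 <- varpart2(rnorm(n), X1, X2)       # y pure noise
  expect_lt(abs(vp2$frac_a), 0.05)
  expect_gt(vp2$frac_d, 0.9)
  expect_error(varpart2(rnorm(n), X1, cbind(X2, X2[, 1])), "collinear")
})

test_that("orthogonal predictors recover their variance shares", {
  set.seed(68)
  n <- 1e4
  x1 <- rnorm(n); x2 <- rnorm(n)
  v1 <- 0.3; v2 <- 0.5
  y <- sqrt(v1) * x1 + sqrt(v2) * x2 + sqrt(1 - v1 - v2) * rnorm(n)
  vp <- varpart2(y, matrix(x1), matrix(x2))
  expect_lt(abs(vp$frac_a - v1), 0.02)
  expect_lt(abs(vp$frac_c - v2), 0.02)
  expect_lt(abs(vp$frac_b), 0.02)
})
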