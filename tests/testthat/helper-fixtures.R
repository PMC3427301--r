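# Shared fixtures and independent brute-force oracles.

# A hand-made valid island table (areas ha, perimeters above the
# equal-area circle bound).
tiny_islands <- function() {
  data.frame(
    id = c("a", "b", "c", "d"),
    area_ha = c(1, 2, 3, 4),
    perimeter_m = c(400, 520, 640, 760),
    dist_mainland_m = c(100, 200, 300, 400),
    stringsAsFactors = FALSE)
}

# Small archipelago with known occupancies.
tiny_arch <- function() {
  isl <- tiny_islands()
  inc <- rbind(
    sp1 = c(1, 0, 0, 0),
    sp2 = c(1, 1, 0, 0),
    sp3 = c(1, 1, 1, 0),
    sp4 = c(1, 1, 1, 1))
  colnames(inc) <- isl$id
  archipelago(isl, inc)
}

# Random valid island table of n rows.
random_islands <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  area <- exp(runif(n, log(0.3), log(60)))
  data.frame(
    id = sprintf("r%03d", seq_len(n)),
    area_ha = area,
    perimeter_m = fragsar:::circle_perimeter(area) * runif(n, 1, 2),
    dist_mainland_m = runif(n, 0, 2000),
    stringsAsFactors = FALSE)
}

# Pearson correlation from explicit sums (no cor()).
bf_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  num / den
}

# Spearman rho: midranks then explicit-sum Pearson.
bf_spearman <- function(x, y) {
  bf_pearson(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"))
}

# Partial rank correlation via the precision matrix of the rank
# correlation matrix (a different route than OLS residuals).
bf_partial_spearman <- function(table, x, y, controls) {
  cols <- c(x, y, controls)
  R <- matrix(0, length(cols), length(cols),
              dimnames = list(cols, cols))
  for (i in seq_along(cols))
    for (j in seq_along(cols))
      R[i, j] <- bf_spearman(table[[cols[i]]], table[[cols[j]]])
  P <- solve(R)
  -P[x, y] / sqrt(P[x, x] * P[y, y])
}

# Variation partitioning via lm() adjusted R2 (independent of the
# package's qr-based path).
bf_varpart <- function(y, X1, X2) {
  ar2 <- function(X) {
    d <- data.frame(y = y, X)
    summary(stats::lm(y ~ ., data = d))$adj.r.squared
  }
  r1 <- ar2(as.data.frame(X1)); r2 <- ar2(as.data.frame(X2))
  rf <- ar2(data.frame(X1, X2))
  c(frac_a = rf - r2, frac_b = r1 + r2 - rf, frac_c = rf - r1,
    frac_d = 1 - rf)
}
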