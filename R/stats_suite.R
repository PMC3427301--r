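# Rank-based correlation analyses and adjusted-R2 variation
# partitioning used to attribute variation in LSAR z-values to
# habitat-area loss versus fragmentation per se.

# Midranks.
mrank <- function(x) rank(x, ties.method = "average")

# Two-sided p from the t approximation for a correlation coefficient.
cor_p_t <- function(r, df) {
  if (df <= 0 || is.na(r)) return(NA_real_)
  r <- max(min(r, 1), -1)
  if (abs(r) == 1) return(0)
  tstat <- r * sqrt(df / (1 - r^2))
  2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
}

#' Pairwise Spearman correlation matrix with Bonferroni correction
#'
#' Spearman rho via midranks followed by Pearson correlation on the
#' ranks; p-values from the t approximation; Bonferroni family = all
#' pairs in the matrix.
#'
#' @param table data.frame of numeric columns (>= 4 rows).
#' @return data.frame with one row per unordered pair: `var_x`,
#'   `var_y`, `rho`, `p_raw`, `p_adj`, `n`. Constant columns yield
#'   `NA` rho with a warning.
#' @export
spearman_matrix <- function(table) {
  stopifnot(is.data.frame(table), nrow(table) >= 4)
  vars <- names(table)
  const <- vars[vapply(table, function(col) stats::var(col) == 0, logical(1))]
  if (length(const) > 0L)
    warning("constant column(s), rho undefined: ",
            paste(const, collapse = ", "))
  ranks <- as.data.frame(lapply(table, mrank))
  n <- nrow(table)
  pairs <- utils::combn(vars, 2)
  m <- ncol(pairs)
  res <- data.frame(var_x = pairs[1, ], var_y = pairs[2, ],
                    rho = NA_real_, p_raw = NA_real_, p_adj = NA_real_,
                    n = n, stringsAsFactors = FALSE)
  for (k in seq_len(m)) {
    x <- ranks[[pairs[1, k]]]; y <- ranks[[pairs[2, k]]]
    if (stats::var(x) == 0 || stats::var(y) == 0) next
    rho <- stats::cor(x, y)
    res$rho[k] <- rho
    res$p_raw[k] <- cor_p_t(rho, n - 2)
  }
  res$p_adj <- pmin(1, res$p_raw * m)
  res
}

#' Partial Spearman correlation
#'
#' All columns are midrank-transformed; the partial correlation of
#' `x` and `y` given `controls` is the Pearson correlation of the OLS
#' residuals of the ranked `x` and ranked `y` on the ranked controls.
#' With empty controls this reduces exactly to the plain Spearman
#' coefficient. p from the t approximation with
#' `df = n - 2 - |controls|`; `p_adj` applies a Bonferroni factor
#' `family_size` (default 1, i.e. unadjusted).
#'
#' @param table data.frame of numeric columns.
#' @param x,y column names.
#' @param controls character vector of control column names (possibly
#'   empty), disjoint from `x` and `y`.
#' @param family_size Bonferroni family size for `p_adj`.
#' @return one-row data.frame: `var_x`, `var_y`, `controls`, `rho`,
#'   `p_raw`, `p_adj`, `n`.
#' @export
partial_spearman <- function(table, x, y, controls = character(0),
                             family_size = 1L) {
  stopifnot(is.data.frame(table),
            all(c(x, y, controls) %in% names(table)))
  if (x %in% controls || y %in% controls)
    stop("controls must be disjoint from x and y")
  n <- nrow(table)
  k <- length(controls)
  if (n <= k + 3) stop("need n > |controls| + 3 observations")
  rx <- mrank(table[[x]]); ry <- mrank(table[[y]])
  if (k > 0) {
    Z <- cbind(1, vapply(controls, function(v) mrank(table[[v]]),
                         numeric(n)))
    qz <- qr(Z)
    if (qz$rank < ncol(Z))
      stop("singular control design: ", paste(controls, collapse = ", "))
    rx <- qr.resid(qz, rx)
    ry <- qr.resid(qz, ry)
  }
  rho <- stats::cor(rx, ry)
  p <- cor_p_t(rho, n - 2 - k)
  data.frame(var_x = x, var_y = y,
             controls = paste(controls, collapse = "+"),
             rho = rho, p_raw = p, p_adj = min(1, p * family_size),
             n = n, stringsAsFactors = FALSE)
}

# Ezekiel adjusted R2 of an OLS fit of y on the columns of X.
adj_r2 <- function(y, X) {
  n <- length(y); p <- ncol(X)
  qx <- qr(cbind(1, X))
  if (qx$rank < p + 1)
    stop("collinear predictor design")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(0)  # constant response: nothing to explain
  res <- qr.resid(qx, y)
  r2 <- 1 - sum(res^2) / ss_tot
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Two-set variation partitioning by adjusted R-squared
#'
#' With a univariate response, redundancy analysis reduces to linear
#' regression, and the partition of explained variation between two
#' predictor sets follows from three adjusted R-squared values:
#' `frac_a` (unique to `X1`), `frac_c` (unique to `X2`), `frac_b`
#' (shared), `frac_d` (unexplained). Fractions sum to 1 by
#' construction; small negative fractions are reported as computed,
#' as is conventional for adjusted-R2 partitions.
#'
#' @param y numeric response.
#' @param X1 matrix/data.frame of the first predictor set (habitat
#'   area).
#' @param X2 matrix/data.frame of the second predictor set
#'   (fragmentation per se: PN, PSV, LSI, MDM).
#' @return list with `frac_a`, `frac_b`, `frac_c`, `frac_d`,
#'   `r2_x1`, `r2_x2`, `r2_full` (all adjusted), `n`.
#' @export
varpart2 <- function(y, X1, X2) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  n <- length(y)
  stopifnot(nrow(X1) == n, nrow(X2) == n)
  p_full <- ncol(X1) + ncol(X2)
  if (n <= p_full + 2)
    stop("need n > ", p_full + 2, " observations for the full model")
  r1 <- adj_r2(y, X1)
  r2 <- adj_r2(y, X2)
  rf <- adj_r2(y, cbind(X1, X2))
  list(frac_a = rf - r2,
       frac_b = r1 + r2 - rf,
       frac_c = rf - r1,
       frac_d = 1 - rf,
       r2_x1 = r1, r2_x2 = r2, r2_full = rf, n = n)
}

#' Phase-wise variation partitioning of z-values
#'
#' Each landscape inherits the z-value of its patch-number level for
#' the given view; within each phase (responsive/stable, from the
#' view's breakpoint fit), the inherited z is partitioned between the
#' landscape's own habitat area (`area_total_ha`) and its
#' fragmentation-per-se attributes (`pn`, `psv`, `lsi`, `mdm_m`) via
#' [varpart2()].
#'
#' @param ens a [build_ensemble()] result.
#' @param zser one view's rows of a [z_series()] data.frame.
#' @param fit the [fit_piecewise()] fit of that view's z series.
#' @return data.frame with one row per phase: `phase`, `frac_a`,
#'   `frac_b`, `frac_c`, `frac_d`, `n`.
#' @export
phase_varpart <- function(ens, zser, fit) {
  stopifnot(inherits(ens, "landscape_ensemble"))
  L <- ens$landscapes
  zmap <- stats::setNames(zser$z, zser$pn_level)
  y <- zmap[as.character(L$pn_level)]
  if (anyNA(y)) stop("z series does not cover all patch-number levels")
  phase <- split_phases(fit, L$pn_level)
  out <- lapply(levels(phase), function(ph) {
    sel <- phase == ph
    X1 <- L[sel, "area_total_ha", drop = FALSE]
    X2 <- L[sel, c("pn", "psv", "lsi", "mdm_m")]
    # a predictor constant within a phase (e.g. pn when the phase
    # holds a single level) carries no information there
    X2 <- X2[, vapply(X2, function(col) stats::var(col) > 0, logical(1)),
             drop = FALSE]
    if (ncol(X2) == 0L || stats::var(X1[[1L]]) == 0)
      return(data.frame(phase = ph, frac_a = NA_real_, frac_b = NA_real_,
                        frac_c = NA_real_, frac_d = NA_real_,
                        n = sum(sel)))
    vp <- varpart2(y[sel], X1, X2)
    data.frame(phase = ph, frac_a = vp$frac_a, frac_b = vp$frac_b,
               frac_c = vp$frac_c, frac_d = vp$frac_d, n = vp$n)
  })
  do.call(rbind, out)
}
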