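# Two-segment continuous piecewise linear regression ("broken stick")
# for locating the threshold patch number that separates the
# responsive phase (few patches, z changes rapidly) from the stable
# phase (many patches, z changes slowly).
#
# Model: y = b0 + b1*x + b2*(x - psi)_+ , continuous at the breakpoint
# psi. For each candidate psi the betas are the OLS solution; psi is
# chosen by a coarse grid over the interior of the x-range (step 0.1)
# followed by golden-section refinement of the SSE profile.

piecewise_design <- function(x, psi) cbind(1, x, pmax(x - psi, 0))

piecewise_sse <- function(x, y, psi) {
  fit <- stats::lm.fit(piecewise_design(x, psi), y)
  sum(fit$residuals^2)
}

golden_section <- function(f, lo, hi, tol = 1e-6) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - phi * (b - a); c2 <- a + phi * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  while (b - a > tol) {
    if (f1 <= f2) {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - phi * (b - a); f1 <- f(c1)
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + phi * (b - a); f2 <- f(c2)
    }
  }
  (a + b) / 2
}

#' Fit a two-segment continuous piecewise regression
#'
#' @param x predictor (patch-number levels), at least 5 distinct
#'   values.
#' @param y response (z-values), same length.
#' @param grid_step coarse-grid spacing for the breakpoint search.
#' @param improvement_min minimum proportional SSE improvement over
#'   the single straight line for the breakpoint to be considered
#'   real; below it the fit is flagged `no_threshold`.
#' @return object of class `"breakpoint_fit"`: `psi`, `beta0`,
#'   `beta1` (slope below psi), `beta2` (slope change above psi),
#'   `r2`, `p` (overall F-test of the 3-parameter model against the
#'   intercept-only model), `no_threshold`, `degenerate`.
#' @export
fit_piecewise <- function(x, y, grid_step = 0.1, improvement_min = 0.01) {
  stopifnot(length(x) == length(y))
  ord <- order(x)
  x <- as.numeric(x[ord]); y <- as.numeric(y[ord])
  if (length(unique(x)) < 5L)
    stop("need at least 5 distinct x values")
  if (stats::var(y) == 0) {
    return(structure(list(psi = NA_real_, beta0 = y[1], beta1 = 0,
                          beta2 = 0, r2 = 0, p = NA_real_,
                          no_threshold = TRUE, degenerate = TRUE,
                          x = x, y = y),
                     class = "breakpoint_fit"))
  }
  # interior candidates: keep >= 2 x-values on each side of psi
  xs <- sort(unique(x))
  lo <- xs[2L]; hi <- xs[length(xs) - 1L]
  grid <- seq(lo, hi, by = grid_step)
  sse_grid <- vapply(grid, function(p) piecewise_sse(x, y, p), numeric(1))
  best <- which.min(sse_grid)
  glo <- grid[max(1L, best - 1L)]; ghi <- grid[min(length(grid), best + 1L)]
  psi <- golden_section(function(p) piecewise_sse(x, y, p), glo, ghi)
  if (piecewise_sse(x, y, grid[best]) < piecewise_sse(x, y, psi))
    psi <- grid[best]
  fit <- stats::lm.fit(piecewise_design(x, psi), y)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  n <- length(x)
  df1 <- 3; df2 <- n - df1 - 1  # psi counts as an estimated parameter
  fstat <- ((ss_tot - ss_res) / df1) / (ss_res / df2)
  p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  # compare against a single straight line
  line <- stats::lm.fit(cbind(1, x), y)
  sse_line <- sum(line$residuals^2)
  # guard against roundoff when both models fit essentially perfectly
  no_thr <- (sse_line - ss_res) <
    improvement_min * sse_line + 1e-12 * ss_tot
  structure(list(psi = psi,
                 beta0 = unname(fit$coefficients[1L]),
                 beta1 = unname(fit$coefficients[2L]),
                 beta2 = unname(fit$coefficients[3L]),
                 r2 = r2, p = p, no_threshold = no_thr,
                 degenerate = FALSE, x = x, y = y),
            class = "breakpoint_fit")
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("Piecewise fit: degenerate (constant response), no breakpoint\n")
  } else {
    cat(sprintf(
      "Piecewise fit: psi = %.2f, slopes %.4g | %.4g, R2 = %.3f, p = %.3g%s\n",
      x$psi, x$beta1, x$beta1 + x$beta2, x$r2, x$p,
      if (x$no_threshold) "  [no clear threshold]" else ""))
  }
  invisible(x)
}

#' Predicted values from a piecewise fit
#' @param object a `breakpoint_fit`.
#' @param newdata optional numeric x values.
#' @param ... unused.
#' @export
predict.breakpoint_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else newdata
  if (object$degenerate) return(rep(object$beta0, length(x)))
  as.vector(piecewise_design(x, object$psi) %*%
              c(object$beta0, object$beta1, object$beta2))
}

#' Split patch-number levels into responsive and stable phases
#'
#' Levels below the breakpoint are "responsive" (z changes rapidly as
#' patches are lost), levels at or above it are "stable". The
#' boundary level rounds toward the stable side so an integer
#' threshold labels the first stable level.
#'
#' @param fit a [fit_piecewise()] result with a defined breakpoint.
#' @param pn_levels integer patch numbers to classify.
#' @return factor with levels `responsive`, `stable`.
#' @export
split_phases <- function(fit, pn_levels) {
  stopifnot(inherits(fit, "breakpoint_fit"))
  if (is.na(fit$psi)) stop("fit has no defined breakpoint")
  phase <- factor(ifelse(pn_levels < fit$psi, "responsive", "stable"),
                  levels = c("responsive", "stable"))
  if (length(unique(phase)) < 2L)
    stop("breakpoint at the edge of the patch-number range: one phase empty")
  phase
}
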