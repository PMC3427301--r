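# Landscape-scale species-area relationship (LSAR).
#
# The power law S = c * A^z is fitted on log10-log10 scale: ordinary
# least squares of log10(pooled landscape richness) on log10(total
# landscape area). z is the slope; c = 10^intercept. Fitted per patch
# number across the resampled landscapes, this yields the z-versus-
# patch-number series whose shape diagnoses the effect of
# fragmentation per se.

#' Fit the power-law species-area relationship
#'
#' OLS of `log10(richness)` on `log10(area)`. Landscapes with zero
#' richness carry no information about the power law on log scale and
#' are excluded (their count is reported).
#'
#' @param area total landscape areas (ha or any fixed unit).
#' @param richness pooled species richness per landscape.
#' @return object of class `"lsar_fit"`: list with `c`, `z`, `r2`,
#'   `n`, `n_excluded`.
#' @export
fit_lsar <- function(area, richness) {
  stopifnot(length(area) == length(richness))
  keep <- richness >= 1
  n_excluded <- sum(!keep)
  x <- log10(area[keep]); y <- log10(richness[keep])
  if (length(x) < 3L)
    stop("need at least 3 landscapes with richness >= 1 (have ",
         length(x), ")")
  if (stats::var(x) == 0)
    stop("zero variance in log10(area): cannot fit a slope")
  fit <- stats::lm.fit(cbind(1, x), y)
  z <- unname(fit$coefficients[2L])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(c = 10^unname(fit$coefficients[1L]), z = z, r2 = r2,
                 n = length(x), n_excluded = n_excluded),
            class = "lsar_fit")
}

#' @export
print.lsar_fit <- function(x, ...) {
  cat(sprintf("LSAR fit: S = %.4g * A^%.4f  (R2 = %.4f, n = %d%s)\n",
              x$c, x$z, x$r2, x$n,
              if (x$n_excluded > 0)
                paste0(", ", x$n_excluded, " zero-richness excluded")
              else ""))
  invisible(x)
}

#' z-versus-patch-number series for one or more incidence views
#'
#' For every patch-number level, pools all sections of the ensemble
#' and fits the LSAR, yielding one z per level. Views backed by
#' replicate null matrices get one fit per replicate, reported as
#' mean and SD across replicates.
#'
#' @param ens a [build_ensemble()] result.
#' @param views named list; each element is either a single incidence
#'   source (archipelago, species view, or matrix) or a list of
#'   replicate matrices (null-model output).
#' @return data.frame with columns `view`, `pn_level`, `z`, `z_sd`,
#'   `mean_richness`, `richness_sd`, `n`, `n_zero` (`z_sd` is `NA`
#'   for single-source views).
#' @export
z_series <- function(ens, views) {
  stopifnot(inherits(ens, "landscape_ensemble"))
  if (is.null(names(views)) || any(!nzchar(names(views))))
    stop("views must be a named list")
  pn <- ens$landscapes$pn_level
  area <- ens$landscapes$area_total_ha
  levels_pn <- sort(unique(pn))
  out <- list()
  for (v in names(views)) {
    src <- views[[v]]
    reps <- if (is.list(src) && !inherits(src, c("archipelago", "species_view")))
      src else list(src)
    rich <- vapply(reps, function(m) ensemble_richness(ens, m),
                   integer(length(pn)))
    for (lev in levels_pn) {
      sel <- pn == lev
      zs <- apply(rich[sel, , drop = FALSE], 2,
                  function(r) fit_lsar(area[sel], r)$z)
      r_all <- as.vector(rich[sel, , drop = FALSE])
      out[[length(out) + 1L]] <- data.frame(
        view = v, pn_level = lev,
        z = mean(zs),
        z_sd = if (length(zs) > 1L) stats::sd(zs) else NA_real_,
        mean_richness = mean(r_all),
        richness_sd = stats::sd(r_all),
        n = sum(sel), n_zero = sum(r_all == 0))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
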