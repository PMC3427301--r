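# Synthetic archipelago generator.
#
# Emulates the statistical structure of a subtropical land-bridge
# island system (the Thousand Island Lake study system): ~150 islands
# with a strongly bottom-heavy size spectrum plus a shallow graded top
# of a few large islands, perimeters exceeding the equal-area circle,
# scalar mainland distances, and a species pool whose occupancy
# distribution is heavy-tailed (about two thirds of species occupying
# <=10% of islands) with a patch-scale species-area slope near
# z = 0.16.

#' Configuration for the synthetic archipelago generator
#'
#' Defaults describe the emulated study system: 152 islands, 383
#' vascular plant species, island areas from a doubly-truncated
#' log-normal spanning roughly 0.2-150 ha with median below 1 ha,
#' and an occupancy distribution with about two thirds rare species.
#'
#' @param n_islands number of islands (>= 2).
#' @param n_species species-pool size (>= 2).
#' @param area_logmean,area_logsd log-scale location and spread of the
#'   island-area distribution (ha).
#' @param area_bounds lower/upper truncation of island areas, ha. The
#'   default spans the sizes of the emulated 152 study islands.
#' @param area_jitter within-stratum jitter of the stratified
#'   (Latin-hypercube-style) quantile draw, in (0, 0.5]. Stratified
#'   sampling guarantees every archipelago exhibits the full graded
#'   size spectrum, which the stratified landscape resampling design
#'   requires.
#' @param shape_logmean,shape_logsd log-normal parameters of the
#'   perimeter inflation factor (how much longer each shoreline is
#'   than its equal-area circle); the factor is lower-truncated at 1.
#' @param dist_max maximum island-to-mainland distance, m (distances
#'   are uniform on `[0, dist_max]`).
#' @param z_patch target patch-scale species-area exponent; the
#'   occupancy model's area coefficient is calibrated against it.
#' @param occupancy_meanlog,occupancy_shape log-normal location/spread
#'   of species' target occupancy proportions (heavy-tailed prevalence;
#'   the default places ~2/3 of species at or below 10% occupancy).
#' @return object of class `"synth_config"`.
#' @export
synth_config <- function(n_islands = 152L, n_species = 383L,
                         area_logmean = log(0.1), area_logsd = 2.5,
                         area_bounds = c(0.2, 150),
                         area_jitter = 0.45,
                         shape_logmean = 0.3, shape_logsd = 0.25,
                         dist_max = 3000,
                         z_patch = 0.16,
                         occupancy_meanlog = log(0.06),
                         occupancy_shape = 1.1) {
  stopifnot(n_islands >= 2, n_species >= 2, area_logsd > 0,
            length(area_bounds) == 2, area_bounds[1] > 0,
            area_bounds[1] < area_bounds[2],
            area_jitter > 0, area_jitter <= 0.5,
            shape_logsd >= 0, dist_max > 0,
            z_patch > 0, z_patch < 1, occupancy_shape > 0)
  structure(list(n_islands = as.integer(n_islands),
                 n_species = as.integer(n_species),
                 area_logmean = area_logmean, area_logsd = area_logsd,
                 area_bounds = area_bounds, area_jitter = area_jitter,
                 shape_logmean = shape_logmean, shape_logsd = shape_logsd,
                 dist_max = dist_max, z_patch = z_patch,
                 occupancy_meanlog = occupancy_meanlog,
                 occupancy_shape = occupancy_shape),
            class = "synth_config")
}

# Stratified quantile draw from a doubly-truncated lognormal: one
# jittered point per probability stratum, returned in random order.
rtrunc_lnorm_stratified <- function(n, meanlog, sdlog, lo, hi, jitter) {
  plo <- stats::plnorm(lo, meanlog, sdlog)
  phi <- stats::plnorm(hi, meanlog, sdlog)
  if (phi - plo < 1e-6)
    stop("area truncation bounds leave less than 1e-6 probability mass")
  u <- (seq_len(n) - 0.5 + stats::runif(n, -jitter, jitter)) / n
  x <- stats::qlnorm(plo + u * (phi - plo), meanlog, sdlog)
  sample(pmin(pmax(x, lo), hi))
}

# Lognormal lower-truncated at `lo` by inverse-CDF.
rtrunc_lnorm_lower <- function(n, meanlog, sdlog, lo) {
  if (sdlog == 0) return(rep(max(exp(meanlog), lo), n))
  plo <- stats::plnorm(lo, meanlog, sdlog)
  stats::qlnorm(plo + stats::runif(n) * (1 - plo), meanlog, sdlog)
}

#' Generate a synthetic island table
#'
#' Areas are a stratified quantile sample of a doubly-truncated
#' log-normal; perimeters inflate the equal-area circle perimeter by a
#' log-normal factor truncated below at 1; mainland distances are
#' uniform.
#'
#' @param cfg a [synth_config()].
#' @return validated island data.frame (`i001`, `i002`, ... ids).
#' @export
generate_islands <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- cfg$n_islands
  area <- rtrunc_lnorm_stratified(n, cfg$area_logmean, cfg$area_logsd,
                                  cfg$area_bounds[1], cfg$area_bounds[2],
                                  cfg$area_jitter)
  infl <- rtrunc_lnorm_lower(n, cfg$shape_logmean, cfg$shape_logsd, 1)
  validate_islands(data.frame(
    id = sprintf("i%03d", seq_len(n)),
    area_ha = area,
    perimeter_m = infl * circle_perimeter(area),
    dist_mainland_m = stats::runif(n, 0, cfg$dist_max),
    stringsAsFactors = FALSE))
}

# Occupancy model: P(species j on island i) =
#   plogis(a_j + b * (log10(area_i) - mean(log10(area)))),
# with a_j = qlogis(q_j) for a heavy-tailed target occupancy q_j.
occupancy_probs <- function(a, b, log_area_c) {
  stats::plogis(outer(a, b * log_area_c, `+`))
}

# Expected patch-scale slope for a candidate area coefficient b:
# OLS slope of E[log10(S_i)] on log10(area_i), with E[log10 S]
# approximated to second order around E[S]
# (E[log10 S] ~ log10 ES - Var(S) / (2 ES^2 ln 10), S_i a sum of
# independent Bernoullis). The analytic expectation removes
# Monte-Carlo noise from calibration.
expected_patch_slope <- function(a, b, log_area) {
  p <- occupancy_probs(a, b, log_area - mean(log_area))
  es <- colSums(p)
  vs <- colSums(p * (1 - p))
  ey <- log10(es) - vs / (2 * es^2 * log(10))
  stats::cov(ey, log_area) / stats::var(log_area)
}

# Bisection of b in [0, 5] so the expected patch-scale slope matches
# cfg$z_patch to `tol`.
calibrate_area_coef <- function(a, log_area, z_target, tol = 0.01) {
  lo <- 0; hi <- 5
  s_lo <- expected_patch_slope(a, lo, log_area)
  s_hi <- expected_patch_slope(a, hi, log_area)
  if (s_lo > z_target) return(0)
  if (s_hi < z_target)
    stop("cannot calibrate area coefficient: slope at b = 5 is ",
         format(s_hi, digits = 3), " < target ", z_target)
  for (iter in 1:60) {
    mid <- (lo + hi) / 2
    s <- expected_patch_slope(a, mid, log_area)
    if (abs(s - z_target) < tol) return(mid)
    if (s < z_target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Generate a synthetic incidence matrix for a set of islands
#'
#' Species receive heavy-tailed target occupancies; presence of each
#' species on each island is an independent Bernoulli draw with
#' probability `plogis(a_j + b * centred log10 area)`, where `b >= 0`
#' is calibrated by bisection so the expected patch-scale
#' log10(richness)-on-log10(area) slope matches `cfg$z_patch`.
#' Afterwards any empty island receives one uniformly chosen species
#' and any absent species one uniformly chosen island, so the result
#' always satisfies the archipelago invariants.
#'
#' @param islands island table.
#' @param cfg a [synth_config()].
#' @return an [archipelago()].
#' @export
generate_incidence <- function(islands, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  islands <- validate_islands(islands)
  n_i <- nrow(islands); n_s <- cfg$n_species
  log_area <- log10(islands$area_ha)
  q <- exp(stats::rnorm(n_s, cfg$occupancy_meanlog, cfg$occupancy_shape))
  q <- pmin(pmax(q, 1 / n_i), 0.95)
  a <- stats::qlogis(q)
  b <- calibrate_area_coef(a, log_area, cfg$z_patch)
  p <- occupancy_probs(a, b, log_area - mean(log_area))
  inc <- matrix(as.integer(stats::runif(n_s * n_i) < p), n_s, n_i,
                dimnames = list(sprintf("sp%03d", seq_len(n_s)), islands$id))
  # patch-up: no empty islands, no globally absent species
  for (j in which(colSums(inc) == 0L))
    inc[sample.int(n_s, 1L), j] <- 1L
  for (s in which(rowSums(inc) == 0L))
    inc[s, sample.int(n_i, 1L)] <- 1L
  out <- archipelago(islands, inc)
  attr(out, "area_coef") <- b
  out
}

#' Generate a complete synthetic archipelago
#'
#' Convenience wrapper: islands then incidence under one configuration.
#' Set the RNG seed with [set.seed()] before calling for
#' reproducibility.
#'
#' @param cfg a [synth_config()].
#' @return an [archipelago()].
#' @export
generate_archipelago <- function(cfg = synth_config()) {
  generate_incidence(generate_islands(cfg), cfg)
}
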