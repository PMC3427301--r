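# Stratified ensemble of simulated fragmented landscapes.
#
# For each patch number pn in [pn_min, pn_max], islands are drawn
# without replacement so that the landscape's total area falls into
# each of n_sections equal-width ("isometric") sections of the
# admissible total-area range, with n_reps replicate landscapes per
# (pn, section) cell. The admissible range defaults to
# [sum of the pn_max smallest areas, sum of the pn_min largest areas]
# so that area distributions overlap across patch numbers.
#
# Draw mechanism per cell, in order of preference:
#   * exact enumeration of qualifying subsets when choose(n, pn) is
#     small (pn <= 3 at n ~ 150): uniform over qualifying subsets with
#     no rejection cost, and exact detection of infeasible cells;
#   * batched rejection sampling (uniform subsets, binned by section):
#     uniform over qualifying subsets;
#   * a feasibility-pruned sequential constructive draw for cells whose
#     acceptance probability is below the rejection budget (in the
#     emulated system: the smallest-area section at pn near pn_max,
#     where a uniform subset almost surely contains too much area).
#     Constructive draws are random but not uniform over qualifying
#     subsets; their count is reported per cell in `n_fallback`.

#' Sampler configuration for the landscape ensemble
#'
#' Defaults reproduce the published design: patch numbers 2-50, five
#' isometric total-area sections, 200 replicates per cell, i.e.
#' 49 x 5 x 200 = 49,000 landscapes.
#'
#' @param pn_min,pn_max patch-number bounds (pn_min >= 2).
#' @param n_sections number of equal-width total-area sections.
#' @param n_reps replicate landscapes per (pn, section) cell.
#' @param area_min,area_max admissible total-area range, ha; `NULL`
#'   derives them from the island table via [derive_area_range()].
#' @param max_tries rejection-sampling budget: uniform subset
#'   proposals per patch-number level before the constructive fill
#'   takes over.
#' @param enum_limit enumerate qualifying subsets exactly when
#'   `choose(n_islands, pn)` does not exceed this.
#' @return object of class `"sampler_config"`.
#' @export
sampler_config <- function(pn_min = 2L, pn_max = 50L, n_sections = 5L,
                           n_reps = 200L, area_min = NULL, area_max = NULL,
                           max_tries = 2e5, enum_limit = 1e6) {
  stopifnot(pn_min >= 2, pn_max >= pn_min, n_sections >= 1, n_reps >= 1,
            max_tries >= 1)
  if (!is.null(area_min) && !is.null(area_max) && area_min >= area_max)
    stop("area_min must be smaller than area_max")
  structure(list(pn_min = as.integer(pn_min), pn_max = as.integer(pn_max),
                 n_sections = as.integer(n_sections),
                 n_reps = as.integer(n_reps),
                 area_min = area_min, area_max = area_max,
                 max_tries = max_tries, enum_limit = enum_limit),
            class = "sampler_config")
}

#' Admissible total-area range for the resampling design
#'
#' Lower bound: the minimal total area of a landscape with `pn_max`
#' patches (sum of the `pn_max` smallest islands). Upper bound: the
#' maximal total area with `pn_min` patches (sum of the `pn_min`
#' largest). This guarantees every patch number can realize totals
#' across one common range.
#'
#' @param islands island table.
#' @param pn_min,pn_max patch-number bounds.
#' @return numeric `c(area_min, area_max)` in ha.
#' @export
derive_area_range <- function(islands, pn_min = 2L, pn_max = 50L) {
  islands <- validate_islands(islands)
  n <- nrow(islands)
  if (pn_max > n)
    stop("pn_max (", pn_max, ") exceeds the number of islands (", n, ")")
  a <- sort(islands$area_ha)
  rng <- c(sum(a[seq_len(pn_max)]), sum(a[n + 1L - seq_len(pn_min)]))
  if (rng[1] >= rng[2])
    stop("degenerate design: minimal ", pn_max, "-patch total (", rng[1],
         " ha) is not below maximal ", pn_min, "-patch total (", rng[2], " ha)")
  rng
}

# Section index of each total; boundaries belong to the lower section,
# the global minimum to section 1. Totals outside [breaks[1], breaks[n]]
# get NA.
section_of <- function(total, breaks) {
  as.integer(cut(total, breaks, include.lowest = TRUE, right = TRUE))
}

#' Draw one landscape by rejection sampling
#'
#' Uniform draws of `pn` islands without replacement, accepted when
#' the total area lies in `bounds`. Errors when `max_tries` draws are
#' exhausted.
#'
#' @param islands island table.
#' @param pn patch number.
#' @param bounds numeric `c(lo, hi)` total-area window, ha.
#' @param max_tries rejection budget.
#' @return integer vector of row indices into `islands`.
#' @export
sample_landscape <- function(islands, pn, bounds, max_tries = 1e5) {
  islands <- validate_islands(islands)
  stopifnot(pn >= 1, pn <= nrow(islands), length(bounds) == 2)
  a <- islands$area_ha
  for (i in seq_len(max_tries)) {
    idx <- sample.int(length(a), pn)
    tot <- sum(a[idx])
    if (tot >= bounds[1] && tot <= bounds[2]) return(sort(idx))
  }
  stop("rejection sampling exhausted ", max_tries, " tries for pn = ", pn,
       ", total-area window [", bounds[1], ", ", bounds[2], "] ha")
}

# Feasibility-pruned sequential constructive draw: pick islands one at
# a time, uniformly among those that keep the target window
# attainable by *some* completion (judged by min/max completion sums,
# a necessary condition). Restarts on the rare dead end. Random but
# not uniform over qualifying subsets.
sample_landscape_guided <- function(areas, pn, lo, hi, restarts = 200L) {
  n <- length(areas)
  ord <- order(areas)
  a_sorted <- areas[ord]
  for (attempt in seq_len(restarts)) {
    avail <- rep(TRUE, n)            # over sorted positions
    chosen <- integer(0)
    cur <- 0
    ok <- TRUE
    for (r in seq(pn, 1)) {
      pos <- which(avail)
      av <- a_sorted[pos]
      m <- length(av)
      if (m < r) { ok <- FALSE; break }
      csum <- cumsum(av)
      # min/max sum of (r-1) remaining islands excluding candidate k
      if (r > 1) {
        min_excl <- ifelse(seq_len(m) <= r - 1, csum[r] - av, csum[r - 1])
        top <- csum[m] - c(0, csum)[m - r + 2]   # sum of r-1 largest
        top_r <- csum[m] - c(0, csum)[m - r + 1] # sum of r largest
        max_excl <- ifelse(seq_len(m) >= m - r + 2, top_r - av, top)
      } else {
        min_excl <- max_excl <- numeric(m)
      }
      adm <- which(cur + av + min_excl <= hi & cur + av + max_excl >= lo)
      if (length(adm) == 0L) { ok <- FALSE; break }
      k <- adm[sample.int(length(adm), 1L)]
      chosen <- c(chosen, pos[k])
      cur <- cur + av[k]
      avail[pos[k]] <- FALSE
    }
    if (ok && cur >= lo && cur <= hi) return(sort(ord[chosen]))
  }
  stop("constructive sampling failed after ", restarts,
       " restarts for pn = ", pn, ", window [", lo, ", ", hi, "] ha")
}

# Enumerate all size-pn subsets (combn), bin their totals by section,
# and draw n_reps independent uniform picks per section. Returns
# list(members = list of index vectors per section, infeasible =
# integer vector of empty sections).
draw_by_enumeration <- function(areas, pn, breaks, n_reps) {
  cmb <- utils::combn(length(areas), pn)
  tot <- colSums(matrix(areas[cmb], nrow = pn))
  sec <- section_of(tot, breaks)
  n_sections <- length(breaks) - 1L
  members <- vector("list", n_sections)
  infeasible <- integer(0)
  for (s in seq_len(n_sections)) {
    pool <- which(!is.na(sec) & sec == s)
    if (length(pool) == 0L) { infeasible <- c(infeasible, s); next }
    picks <- pool[sample.int(length(pool), n_reps, replace = TRUE)]
    members[[s]] <- lapply(picks, function(j) cmb[, j])
  }
  list(members = members, infeasible = infeasible)
}

# Batched rejection for one pn level, filling all sections from one
# uniform proposal stream; shortfalls go to the constructive sampler.
draw_by_rejection <- function(areas, pn, breaks, n_reps, max_tries) {
  n <- length(areas)
  n_sections <- length(breaks) - 1L
  got <- vector("list", n_sections)
  for (s in seq_len(n_sections)) got[[s]] <- vector("list", 0L)
  need <- rep(n_reps, n_sections)
  tries <- 0
  batch <- 4096L
  while (any(need > 0L) && tries < max_tries) {
    b <- as.integer(min(batch, max_tries - tries))
    idx <- matrix(0L, pn, b)
    for (j in seq_len(b)) idx[, j] <- sample.int(n, pn)
    tot <- colSums(matrix(areas[idx], nrow = pn))
    sec <- section_of(tot, breaks)
    tries <- tries + b
    for (s in which(need > 0L)) {
      hits <- which(!is.na(sec) & sec == s)
      if (length(hits) == 0L) next
      take <- hits[seq_len(min(length(hits), need[s]))]
      got[[s]] <- c(got[[s]], lapply(take, function(j) sort(idx[, j])))
      need[s] <- need[s] - length(take)
    }
  }
  n_fallback <- rep(0L, n_sections)
  for (s in which(need > 0L)) {
    fills <- lapply(seq_len(need[s]), function(k)
      sample_landscape_guided(areas, pn, breaks[s], breaks[s + 1L]))
    got[[s]] <- c(got[[s]], fills)
    n_fallback[s] <- need[s]
  }
  list(members = got, n_fallback = n_fallback)
}

#' Build the stratified ensemble of simulated landscapes
#'
#' @param islands island table (an [archipelago()] is also accepted).
#' @param cfg a [sampler_config()].
#' @param on_infeasible `"error"` aborts when a (pn, section) cell has
#'   no qualifying subset (detectable exactly for enumerated patch
#'   numbers); `"skip"` drops the cell with a warning.
#' @return object of class `"landscape_ensemble"`: list with
#'   * `landscapes`: data.frame `pn_level`, `section`, `rep`,
#'     `area_total_ha`, `pn`, `psv`, `lsi`, `mdm_m`, `n_fallback`;
#'   * `members`: list of island row-index vectors, one per landscape;
#'   * `islands`: the island table; `breaks`: section boundaries;
#'   * `area_range`: the admissible range used.
#' @export
build_ensemble <- function(islands, cfg = sampler_config(),
                           on_infeasible = c("error", "skip")) {
  on_infeasible <- match.arg(on_infeasible)
  if (inherits(islands, "archipelago")) islands <- islands$islands
  islands <- validate_islands(islands)
  stopifnot(inherits(cfg, "sampler_config"))
  if (cfg$pn_max > nrow(islands))
    stop("pn_max exceeds the number of islands")
  rng <- if (is.null(cfg$area_min) || is.null(cfg$area_max))
    derive_area_range(islands, cfg$pn_min, cfg$pn_max)
  else c(cfg$area_min, cfg$area_max)
  breaks <- seq(rng[1], rng[2], length.out = cfg$n_sections + 1L)
  areas <- islands$area_ha
  pn_levels <- seq(cfg$pn_min, cfg$pn_max)

  members <- list()
  rows <- list()
  for (pn in pn_levels) {
    use_enum <- choose(nrow(islands), pn) <= cfg$enum_limit
    drawn <- if (use_enum)
      draw_by_enumeration(areas, pn, breaks, cfg$n_reps)
    else
      draw_by_rejection(areas, pn, breaks, cfg$n_reps, cfg$max_tries)
    if (use_enum && length(drawn$infeasible) > 0L) {
      msg <- paste0("no subset of ", pn, " islands has total area in ",
                    "section(s) ", paste(drawn$infeasible, collapse = ", "))
      if (on_infeasible == "error") stop(msg) else warning(msg)
    }
    fb <- if (use_enum) rep(0L, cfg$n_sections) else drawn$n_fallback
    for (s in seq_len(cfg$n_sections)) {
      ms <- drawn$members[[s]]
      if (length(ms) == 0L) next
      members <- c(members, ms)
      rows[[length(rows) + 1L]] <- data.frame(
        pn_level = pn, section = s, rep = seq_along(ms),
        n_fallback = fb[s])
    }
  }
  meta <- do.call(rbind, rows)
  attrs <- landscape_attributes_many(islands, members)
  landscapes <- cbind(meta[c("pn_level", "section", "rep")], attrs,
                      n_fallback = meta$n_fallback)
  rownames(landscapes) <- NULL
  structure(list(landscapes = landscapes, members = members,
                 islands = islands, breaks = breaks, area_range = rng),
            class = "landscape_ensemble")
}

#' @export
print.landscape_ensemble <- function(x, ...) {
  cat("Landscape ensemble: ", nrow(x$landscapes), " landscapes, pn ",
      min(x$landscapes$pn_level), "-", max(x$landscapes$pn_level),
      ", ", length(x$breaks) - 1L, " area sections over [",
      format(x$area_range[1], digits = 4), ", ",
      format(x$area_range[2], digits = 5), "] ha\n", sep = "")
  nf <- sum(x$landscapes$n_fallback > 0)
  if (nf > 0) cat("  ", nf, "landscapes in cells using constructive fill\n")
  invisible(x)
}

#' Pooled species richness of each landscape
#'
#' Richness of a landscape is the number of species present on at
#' least one member island, computed for any incidence view (observed
#' archipelago, rare/common subset, or a randomized matrix).
#'
#' @param ens a [build_ensemble()] result.
#' @param view an archipelago, species view, or incidence matrix whose
#'   columns follow the ensemble's island order.
#' @return integer vector, one richness per landscape.
#' @export
ensemble_richness <- function(ens, view) {
  stopifnot(inherits(ens, "landscape_ensemble"))
  inc <- incidence_of(view)
  if (ncol(inc) != nrow(ens$islands))
    stop("incidence has ", ncol(inc), " islands, ensemble has ",
         nrow(ens$islands))
  L <- length(ens$members)
  mem <- Matrix::sparseMatrix(
    i = unlist(ens$members, use.names = FALSE),
    j = rep.int(seq_len(L), lengths(ens$members)),
    x = 1, dims = c(nrow(ens$islands), L))
  counts <- Matrix::Matrix(inc, sparse = TRUE) %*% mem
  as.integer(Matrix::colSums(counts > 0))
}
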