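# End-to-end analysis: archipelago -> stratified landscape ensemble ->
# z-series per incidence view -> breakpoints and phases ->
# correlations and variation partitioning -> CSV outputs.

#' Derive a deterministic per-stage seed from the global seed
#'
#' Keeps the seed stream of each pipeline stage independent, so adding
#' or removing a view does not perturb the randomness of the others.
#'
#' @param seed global integer seed.
#' @param stage stage name (character).
#' @return integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1e6
  as.integer((abs(as.numeric(seed)) %% 2^31 * 1000003 + h) %% 2147483647)
}

#' Pipeline configuration
#'
#' Exactly one of `islands_path`/`incidence_path` (observed data) or
#' `synth` (generator settings) drives the run.
#'
#' @param islands_path,incidence_path CSV inputs (see
#'   [read_island_table()], [read_incidence()]); both or neither.
#' @param synth a [synth_config()] used when no input paths are given.
#' @param sampler a [sampler_config()].
#' @param null_replicates randomized matrices per null model for the
#'   z-series (replicate mean and SD are reported).
#' @param views subset of `c("observed", "RDM", "OWRDM", "rare",
#'   "common")`.
#' @param seed global seed; per-stage seeds derive from it.
#' @return object of class `"run_config"`.
#' @export
run_config <- function(islands_path = NULL, incidence_path = NULL,
                       synth = synth_config(), sampler = sampler_config(),
                       null_replicates = 10L,
                       views = c("observed", "RDM", "OWRDM", "rare",
                                 "common"),
                       seed = 1L) {
  has_paths <- !is.null(islands_path) || !is.null(incidence_path)
  if (has_paths && (is.null(islands_path) || is.null(incidence_path)))
    stop("provide both islands_path and incidence_path, or neither")
  views <- match.arg(views, several.ok = TRUE)
  structure(list(islands_path = islands_path,
                 incidence_path = incidence_path,
                 synth = synth, sampler = sampler,
                 null_replicates = as.integer(null_replicates),
                 views = views, seed = as.integer(seed)),
            class = "run_config")
}

# Incidence sources per requested view.
build_views <- function(arch, cfg) {
  out <- list()
  for (v in cfg$views) {
    out[[v]] <- switch(v,
      observed = arch,
      rare = subset_incidence(arch, "rare"),
      common = subset_incidence(arch, "common"),
      RDM = , OWRDM = {
        set.seed(stage_seed(cfg$seed, paste0("null_", v)))
        randomize_incidence(arch, v, cfg$null_replicates)
      })
  }
  out
}

#' Run the full fragmentation analysis
#'
#' Stages: load or generate the archipelago; classify species; build
#' the stratified landscape ensemble; randomize incidence for the null
#' views; compute the z-versus-patch-number series per view; fit the
#' piecewise threshold per view; compute attribute correlations
#' (pairwise Spearman and partial Spearman given PN or Area) on the
#' observed view; partition z variation between area and fragmentation
#' per se within each phase for the all/rare/common views.
#'
#' @param cfg a [run_config()].
#' @param outdir output directory (created if missing); `NULL` skips
#'   all file output.
#' @return invisible list with `arch`, `species`, `ensemble`,
#'   `zseries`, `breakpoints`, `table1`, `table2`, `varpart`,
#'   `manifest`.
#' @export
run_fragmentation_analysis <- function(cfg = run_config(), outdir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  t0 <- Sys.time()
  if (!is.null(cfg$islands_path)) {
    islands <- read_island_table(cfg$islands_path)
    arch <- read_incidence(cfg$incidence_path, islands)
  } else {
    set.seed(stage_seed(cfg$seed, "synth"))
    arch <- generate_archipelago(cfg$synth)
  }
  species <- classify_species(arch)

  set.seed(stage_seed(cfg$seed, "ensemble"))
  ens <- build_ensemble(arch, cfg$sampler)

  views <- build_views(arch, cfg)
  zser <- z_series(ens, views)

  breakpoints <- list()
  for (v in cfg$views) {
    rows <- zser[zser$view == v, ]
    breakpoints[[v]] <- fit_piecewise(rows$pn_level, rows$z)
  }

  # correlations on the observed view: per-landscape attributes plus
  # observed richness and the inherited z of each landscape's pn level
  attr_tab <- ens$landscapes[, c("area_total_ha", "pn", "psv", "lsi",
                                 "mdm_m")]
  names(attr_tab) <- c("Area", "PN", "PSV", "LSI", "MDM")
  table1 <- spearman_matrix(attr_tab)
  obs_rows <- zser[zser$view == "observed", ]
  table2 <- NULL
  if (nrow(obs_rows) > 0L) {
    attr_tab$richness <- ensemble_richness(ens, arch)
    zmap <- stats::setNames(obs_rows$z, obs_rows$pn_level)
    attr_tab$z <- unname(zmap[as.character(ens$landscapes$pn_level)])
    rows <- list()
    for (ctrl in c("PN", "Area")) {
      preds <- setdiff(c("Area", "PN", "PSV", "LSI", "MDM"), ctrl)
      for (resp in c("richness", "z"))
        for (pr in preds)
          rows[[length(rows) + 1L]] <-
            partial_spearman(attr_tab, pr, resp, ctrl,
                             family_size = length(preds))
    }
    table2 <- do.call(rbind, rows)
  }

  vp <- NULL
  vp_views <- intersect(c("observed", "rare", "common"), cfg$views)
  vp_rows <- list()
  for (v in vp_views) {
    fit <- breakpoints[[v]]
    if (is.na(fit$psi)) next
    res <- phase_varpart(ens, zser[zser$view == v, ], fit)
    res <- cbind(view = v, res)
    vp_rows[[length(vp_rows) + 1L]] <- res
  }
  if (length(vp_rows) > 0L) vp <- do.call(rbind, vp_rows)

  manifest <- c(
    sprintf("seed=%d", cfg$seed),
    sprintf("input=%s", if (is.null(cfg$islands_path)) "synthetic"
            else cfg$islands_path),
    sprintf("n_islands=%d", nrow(arch$islands)),
    sprintf("n_species=%d", nrow(arch$incidence)),
    sprintf("pn_range=%d-%d", cfg$sampler$pn_min, cfg$sampler$pn_max),
    sprintf("n_sections=%d", cfg$sampler$n_sections),
    sprintf("n_reps=%d", cfg$sampler$n_reps),
    sprintf("n_landscapes=%d", nrow(ens$landscapes)),
    sprintf("area_range=%.6g,%.6g", ens$area_range[1], ens$area_range[2]),
    sprintf("null_replicates=%d", cfg$null_replicates),
    sprintf("views=%s", paste(cfg$views, collapse = ",")),
    sprintf("elapsed_s=%.1f", as.numeric(difftime(Sys.time(), t0,
                                                  units = "secs"))))

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_island_table(arch$islands, file.path(outdir, "islands.csv"))
    write_incidence(arch, file.path(outdir, "incidence.csv"))
    utils::write.csv(species, file.path(outdir, "species_classes.csv"),
                     row.names = FALSE)
    lands <- ens$landscapes
    lands$island_ids <- vapply(ens$members, function(ix)
      paste(arch$islands$id[ix], collapse = ";"), character(1))
    utils::write.csv(lands, file.path(outdir, "landscapes.csv"),
                     row.names = FALSE)
    for (v in cfg$views)
      utils::write.csv(zser[zser$view == v, ],
                       file.path(outdir, sprintf("zseries_%s.csv", v)),
                       row.names = FALSE)
    bp <- do.call(rbind, lapply(cfg$views, function(v) {
      f <- breakpoints[[v]]
      data.frame(view = v, psi = f$psi, beta0 = f$beta0, beta1 = f$beta1,
                 beta2 = f$beta2, r2 = f$r2, p = f$p,
                 no_threshold = f$no_threshold)
    }))
    utils::write.csv(bp, file.path(outdir, "breakpoints.csv"),
                     row.names = FALSE)
    utils::write.csv(table1, file.path(outdir, "table1.csv"),
                     row.names = FALSE)
    if (!is.null(table2))
      utils::write.csv(table2, file.path(outdir, "table2.csv"),
                       row.names = FALSE)
    if (!is.null(vp))
      utils::write.csv(vp, file.path(outdir, "varpart.csv"),
                       row.names = FALSE)
    writeLines(manifest, file.path(outdir, "run_manifest.txt"))
  }

  invisible(list(arch = arch, species = species, ensemble = ens,
                 zseries = zser, breakpoints = breakpoints,
                 table1 = table1, table2 = table2, varpart = vp,
                 manifest = manifest))
}
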