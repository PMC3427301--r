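# Incidence null models preserving per-island richness.
#
# RDM (random distribution model): each island keeps its observed
# richness S_i but the identities of its species are redrawn uniformly
# without replacement from the full pool, independently per island.
#
# OWRDM (occurrence-weighted RDM): as RDM, but each successive draw
# selects a species with probability proportional to its observed
# occupancy proportion among the species not yet drawn for that
# island.

#' Randomize an incidence matrix under RDM or OWRDM
#'
#' @param arch an [archipelago()].
#' @param model `"RDM"` or `"OWRDM"`.
#' @param n_replicates number of independent randomized matrices.
#' @return list of incidence matrices (same dimnames as the observed
#'   matrix); per-island richness equals the observed richness in
#'   every replicate.
#' @export
randomize_incidence <- function(arch, model = c("RDM", "OWRDM"),
                                n_replicates = 100L) {
  model <- match.arg(model)
  stopifnot(inherits(arch, "archipelago"), n_replicates >= 1)
  inc <- arch$incidence
  n_sp <- nrow(inc); n_is <- ncol(inc)
  s_obs <- colSums(inc)
  if (any(s_obs > n_sp))
    stop("island richness exceeds the species pool")  # unreachable for 0/1
  w <- if (model == "OWRDM") rowSums(inc) / n_is else NULL
  lapply(seq_len(n_replicates), function(r) {
    out <- matrix(0L, n_sp, n_is, dimnames = dimnames(inc))
    for (j in seq_len(n_is)) {
      picked <- if (is.null(w))
        sample.int(n_sp, s_obs[j])
      else
        sample.int(n_sp, s_obs[j], prob = w)  # successive weighted draws
      out[picked, j] <- 1L
    }
    out
  })
}
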