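# Landscape attributes of a set of islands.
#
# Area  = total land-surface area (ha)
# PN    = patch number
# PSV   = patch size variability: coefficient of variation of patch
#         area (sample SD / mean, as a ratio; 0 for a single patch)
# LSI   = landscape shape index E/minE, where E is the summed edge
#         length (m) and minE the perimeter of the single circle whose
#         area equals the total landscape area
# MDM   = mean island-edge-to-mainland distance (m)

#' Landscape attributes of an island set
#'
#' @param islands nonempty island table (see [validate_islands()]).
#' @return one-row data.frame with columns `area_total_ha`, `pn`,
#'   `psv`, `lsi`, `mdm_m`.
#' @examples
#' sq <- data.frame(id = "a", area_ha = 1, perimeter_m = 400,
#'                  dist_mainland_m = 100)
#' landscape_attributes(sq)  # lsi = 400 / (2*sqrt(pi*1e4)) = 2/sqrt(pi)
#' @export
landscape_attributes <- function(islands) {
  islands <- validate_islands(islands)
  if (nrow(islands) == 0L) stop("empty island collection")
  a <- islands$area_ha
  total <- sum(a)
  psv <- if (length(a) == 1L) 0 else stats::sd(a) / mean(a)
  data.frame(
    area_total_ha = total,
    pn = nrow(islands),
    psv = psv,
    lsi = sum(islands$perimeter_m) / circle_perimeter(total),
    mdm_m = mean(islands$dist_mainland_m))
}

# Vectorized attributes for many landscapes over one island table.
# `members` is a list of integer index vectors into `islands`.
# Avoids per-landscape data.frame overhead in large ensembles.
landscape_attributes_many <- function(islands, members) {
  a <- islands$area_ha; per <- islands$perimeter_m
  d <- islands$dist_mainland_m
  n <- lengths(members)
  idx <- unlist(members, use.names = FALSE)
  grp <- rep.int(seq_along(members), n)
  tot <- as.numeric(rowsum(a[idx], grp, reorder = TRUE))
  sum2 <- as.numeric(rowsum(a[idx]^2, grp, reorder = TRUE))
  mean_a <- tot / n
  # sample variance from sums; guard pn = 1 and tiny negatives
  v <- ifelse(n > 1L, pmax(sum2 - n * mean_a^2, 0) / (n - 1L), 0)
  data.frame(
    area_total_ha = tot,
    pn = as.integer(n),
    psv = ifelse(n > 1L, sqrt(v) / mean_a, 0),
    lsi = as.numeric(rowsum(per[idx], grp)) / circle_perimeter(tot),
    mdm_m = as.numeric(rowsum(d[idx], grp)) / n)
}
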