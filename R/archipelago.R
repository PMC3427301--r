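# Domain containers and CSV input/output for island systems.
#
# An island table is a data.frame with one row per habitat patch:
#   id (character), area_ha, perimeter_m, dist_mainland_m.
# An archipelago couples an island table with a species x island 0/1
# incidence matrix (rows = species, columns = islands).

# Perimeter of the circle enclosing `area_ha` hectares, in meters.
# 1 ha = 1e4 m^2, so minE = 2*sqrt(pi * A * 1e4).
circle_perimeter <- function(area_ha) 2 * sqrt(pi * area_ha * 1e4)

#' Validate an island table
#'
#' Checks the structural invariants every island table must satisfy:
#' required columns, unique ids, positive area and perimeter,
#' non-negative mainland distance, and the geometric lower bound
#' `perimeter >= 2*sqrt(pi * area * 1e4)` (no patch can have less edge
#' than the circle of equal area).
#'
#' @param islands data.frame with columns `id`, `area_ha`,
#'   `perimeter_m`, `dist_mainland_m`.
#' @param tol relative tolerance for the circle-perimeter bound.
#' @return the validated data.frame, invisibly unchanged (ids coerced
#'   to character).
#' @export
validate_islands <- function(islands, tol = 1e-9) {
  required <- c("id", "area_ha", "perimeter_m", "dist_mainland_m")
  missing <- setdiff(required, names(islands))
  if (length(missing) > 0L)
    stop("island table is missing column(s): ", paste(missing, collapse = ", "))
  islands$id <- as.character(islands$id)
  if (anyDuplicated(islands$id))
    stop("duplicate island id(s): ",
         paste(unique(islands$id[duplicated(islands$id)]), collapse = ", "))
  for (col in c("area_ha", "perimeter_m", "dist_mainland_m")) {
    if (!is.numeric(islands[[col]]) || anyNA(islands[[col]]))
      stop("column ", col, " must be numeric with no missing values")
  }
  bad <- which(islands$area_ha <= 0 | islands$perimeter_m <= 0)
  if (length(bad) > 0L)
    stop("non-positive area or perimeter in row(s): ",
         paste(bad, collapse = ", "))
  bad <- which(islands$dist_mainland_m < 0)
  if (length(bad) > 0L)
    stop("negative mainland distance in row(s): ", paste(bad, collapse = ", "))
  min_per <- circle_perimeter(islands$area_ha)
  bad <- which(islands$perimeter_m < min_per * (1 - tol))
  if (length(bad) > 0L)
    stop("perimeter below the equal-area circle perimeter in row(s): ",
         paste(bad, collapse = ", "),
         " (e.g. row ", bad[1L], ": ", islands$perimeter_m[bad[1L]], " m < ",
         format(min_per[bad[1L]], digits = 8), " m)")
  islands
}

#' Construct an archipelago
#'
#' Couples a validated island table with a species x island
#' presence/absence matrix. Incidence columns are aligned to the
#' island-table order by name. Every island must hold at least one
#' species and every species must occur on at least one island.
#'
#' @param islands island table (see [validate_islands()]).
#' @param incidence numeric/logical matrix, rows = species (rownames =
#'   species ids), columns = islands (colnames = island ids), entries
#'   0/1.
#' @return an object of class `"archipelago"`: a list with elements
#'   `islands` (data.frame) and `incidence` (integer matrix).
#' @export
archipelago <- function(islands, incidence) {
  islands <- validate_islands(islands)
  if (!is.matrix(incidence))
    stop("incidence must be a matrix")
  if (is.null(rownames(incidence)) || is.null(colnames(incidence)))
    stop("incidence must carry species rownames and island colnames")
  if (anyDuplicated(rownames(incidence)))
    stop("duplicate species id(s) in incidence")
  unknown <- setdiff(colnames(incidence), islands$id)
  if (length(unknown) > 0L)
    stop("incidence column(s) not in island table: ",
         paste(unknown, collapse = ", "))
  if (ncol(incidence) != nrow(islands))
    stop("incidence has ", ncol(incidence), " island columns but the island ",
         "table has ", nrow(islands), " rows")
  incidence <- incidence[, islands$id, drop = FALSE]
  storage.mode(incidence) <- "integer"
  if (!all(incidence %in% c(0L, 1L)))
    stop("incidence entries must be 0 or 1")
  empty_sp <- rownames(incidence)[rowSums(incidence) == 0L]
  if (length(empty_sp) > 0L)
    stop("species with no occurrences: ", paste(empty_sp, collapse = ", "))
  empty_is <- colnames(incidence)[colSums(incidence) == 0L]
  if (length(empty_is) > 0L)
    stop("island(s) with no species: ", paste(empty_is, collapse = ", "))
  structure(list(islands = islands, incidence = incidence),
            class = "archipelago")
}

#' @export
print.archipelago <- function(x, ...) {
  cat("Archipelago: ", nrow(x$islands), " islands, ",
      nrow(x$incidence), " species, ",
      sum(x$incidence), " occurrences\n", sep = "")
  cat("  area ", format(min(x$islands$area_ha), digits = 3), "-",
      format(max(x$islands$area_ha), digits = 5), " ha, total ",
      format(sum(x$islands$area_ha), digits = 6), " ha\n", sep = "")
  invisible(x)
}

#' Read an island table from CSV
#'
#' Expects a header row with columns `id`, `area_ha`, `perimeter_m`,
#' `dist_mainland_m`; rows are kept in file order.
#'
#' @param path file path.
#' @return validated island data.frame.
#' @export
read_island_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(id = "character"))
  validate_islands(df)
}

#' Write an island table to CSV
#' @param islands island table.
#' @param path file path.
#' @export
write_island_table <- function(islands, path) {
  islands <- validate_islands(islands)
  utils::write.csv(
    islands[, c("id", "area_ha", "perimeter_m", "dist_mainland_m")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a species x island incidence matrix from CSV
#'
#' First column holds species ids; every remaining column is named by
#' an island id from `islands`. Cells must be 0/1. Columns may appear
#' in any order; they are realigned to the island-table order.
#'
#' @param path file path.
#' @param islands island table the columns must match.
#' @return an [archipelago()].
#' @export
read_incidence <- function(path, islands) {
  islands <- validate_islands(islands)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  if (ncol(df) < 2L)
    stop("incidence file needs a species id column plus island columns")
  sp <- df[[1L]]
  mat <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.integer(mat), nrow(mat), ncol(mat),
                                 dimnames = list(sp, colnames(mat))))
  if (anyNA(num)) stop("non-numeric incidence cell(s)")
  archipelago(islands, num)
}

#' Write incidence to CSV
#' @param arch an archipelago (or a 0/1 matrix with dimnames).
#' @param path file path.
#' @export
write_incidence <- function(arch, path) {
  inc <- if (inherits(arch, "archipelago")) arch$incidence else arch
  df <- data.frame(species_id = rownames(inc), inc, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Occupancy cutoff for "rare" species
#'
#' A species is rare when it occupies at most 10% of the islands,
#' i.e. at most `floor(0.10 * n_islands)` islands (for 152 islands the
#' cutoff is 15).
#'
#' @param n_islands number of islands in the system.
#' @return integer cutoff.
#' @export
rare_cutoff <- function(n_islands) as.integer(floor(0.10 * n_islands))

#' Classify species as rare or common by island occupancy
#'
#' @param arch an archipelago.
#' @return data.frame with columns `species_id`, `n_islands`,
#'   `proportion`, `class` (factor rare/common), one row per species
#'   in incidence row order.
#' @export
classify_species <- function(arch) {
  stopifnot(inherits(arch, "archipelago"))
  n_tot <- nrow(arch$islands)
  occ <- rowSums(arch$incidence)
  cut <- rare_cutoff(n_tot)
  data.frame(
    species_id = rownames(arch$incidence),
    n_islands = as.integer(occ),
    proportion = occ / n_tot,
    class = factor(ifelse(occ <= cut, "rare", "common"),
                   levels = c("rare", "common")),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Restrict an archipelago to one occupancy class of species
#'
#' Islands are never dropped: an island whose species all fall outside
#' the requested class keeps its row (and hence its geometry) with an
#' all-zero incidence column. The result is therefore not a strict
#' archipelago (its invariants allow empty islands) and is returned as
#' a plain list with the same shape.
#'
#' @param arch an archipelago.
#' @param cls one of `"all"`, `"rare"`, `"common"`.
#' @return for `"all"`, `arch` unchanged; otherwise a list with
#'   elements `islands` and `incidence` (species subset).
#' @export
subset_incidence <- function(arch, cls = c("all", "rare", "common")) {
  cls <- match.arg(cls)
  stopifnot(inherits(arch, "archipelago"))
  if (cls == "all") return(arch)
  keep <- classify_species(arch)$class == cls
  if (!any(keep)) stop("no species in class '", cls, "'")
  structure(list(islands = arch$islands,
                 incidence = arch$incidence[keep, , drop = FALSE]),
            class = "species_view")
}

# Incidence matrix of any archipelago-like object.
incidence_of <- function(x) {
  if (is.matrix(x)) x else x$incidence
}
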