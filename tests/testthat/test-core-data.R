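test_that("island table CSV round trip preserves order and values", {
  isl <- tiny_islands()
  path <- withr::local_tempfile(fileext = ".csv")
  write_island_table(isl, path)
  back <- read_island_table(path)
  expect_identical(back$id, isl$id)
  expect_equal(back$area_ha, isl$area_ha, tolerance = 1e-12)
  expect_equal(back$perimeter_m, isl$perimeter_m, tolerance = 1e-12)
  expect_equal(back$dist_mainland_m, isl$dist_mainland_m, tolerance = 1e-12)
})

test_that("island validation rejects bad rows with informative errors", {
  isl <- tiny_islands()
  expect_error(validate_islands(isl[, -2]), "area_ha")
  bad <- isl; bad$area_ha[2] <- 0
  expect_error(validate_islands(bad), "row\\(s\\): 2")
  # a 1 ha island cannot have a 300 m shoreline: the equal-area circle
  # already needs 2*sqrt(pi*1e4) ~ 354.49 m
  bad <- isl; bad$perimeter_m[1] <- 300
  expect_error(validate_islands(bad), "equal-area circle")
  expect_gt(fragsar:::circle_perimeter(1), 354.49)
  expect_lt(fragsar:::circle_perimeter(1), 354.50)
  bad <- isl; bad$id[2] <- "a"
  expect_error(validate_islands(bad), "duplicate")
})

test_that("incidence reader aligns permuted columns to island order", {
  isl <- tiny_islands()
  inc <- matrix(1L, 2, 4, dimnames = list(c("s1", "s2"), isl$id))
  path <- withr::local_tempfile(fileext = ".csv")
  write_incidence(inc, path)
  arch1 <- read_incidence(path, isl)
  expect_equal(sum(arch1$incidence), 8)
  # permute columns in the file; the archipelago must be identical
  perm <- inc[, c(3, 1, 4, 2)]
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_incidence(perm, path2)
  arch2 <- read_incidence(path2, isl)
  expect_identical(arch1$incidence, arch2$incidence)
})

test_that("incidence validation rejects empty species and unknown islands", {
  isl <- tiny_islands()
  inc <- rbind(s1 = c(1L, 1L, 1L, 1L), s2 = c(0L, 0L, 0L, 0L))
  colnames(inc) <- isl$id
  expect_error(archipelago(isl, inc), "s2")
  inc2 <- matrix(1L, 1, 5,
                 dimnames = list("s1", c(isl$id, "ghost")))
  expect_error(archipelago(isl, inc2), "ghost")
})

test_that("rare/common classification uses the floor(10%) cutoff", {
  expect_identical(rare_cutoff(152), 15L)
  expect_identical(rare_cutoff(10), 1L)
  # synthetic occupancies 1, 15, 16, 152 over 152 islands
  n <- 152
  isl <- random_islands(n, seed = 1)
  inc <- rbind(
    s_occ1 = c(1L, rep(0L, n - 1)),
    s_occ15 = c(rep(1L, 15), rep(0L, n - 15)),
    s_occ16 = c(rep(1L, 16), rep(0L, n - 16)),
    s_all = rep(1L, n))
  colnames(inc) <- isl$id
  cls <- classify_species(archipelago(isl, inc))
  expect_identical(as.character(cls$class),
                   c("rare", "rare", "common", "common"))
  expect_identical(cls$n_islands, c(1L, 15L, 16L, 152L))
})

test_that("rare and common subsets partition the species pool", {
  arch <- tiny_arch()  # cutoff floor(0.4) = 0: every species common
  expect_identical(subset_incidence(arch, "all"), arch)
  set.seed(3)
  isl <- random_islands(30)
  inc <- matrix(rbinom(40 * 30, 1, 0.15), 40, 30,
                dimnames = list(sprintf("s%02d", 1:40), isl$id))
  inc[cbind(sample.int(40, 30, replace = TRUE), 1:30)] <- 1L
  inc[cbind(1:40, sample.int(30, 40, replace = TRUE))] <- 1L
  arch <- archipelago(isl, inc)
  rare <- subset_incidence(arch, "rare")
  common <- subset_incidence(arch, "common")
  expect_identical(
    sort(c(rownames(rare$incidence), rownames(common$incidence))),
    sort(rownames(arch$incidence)))
  expect_length(
    intersect(rownames(rare$incidence), rownames(common$incidence)), 0)
  # islands are retained even when a class empties them
  expect_identical(rare$islands, arch$islands)
  # classification depends only on row sums: idempotent under column
  # permutation of incidence
  perm <- sample(ncol(inc))
  arch_p <- archipelago(isl[perm, ], inc[, perm])
  cls_a <- classify_species(arch)
  cls_p <- classify_species(arch_p)
  expect_identical(cls_a$class, cls_p$class)
})
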