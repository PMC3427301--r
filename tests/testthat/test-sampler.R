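test_that("derive_area_range matches direct enumeration", {
  isl <- tiny_islands()  # areas 1, 2, 3, 4
  expect_equal(derive_area_range(isl, pn_min = 2, pn_max = 3), c(6, 7))
  # all-equal areas make the design degenerate for pn_max > 2
  eq <- data.frame(id = letters[1:4], area_ha = 2, perimeter_m = 600,
                   dist_mainland_m = 0)
  expect_error(derive_area_range(eq, 2, 3), "degenerate")
  expect_error(derive_area_range(isl, 2, 5), "exceeds")
})

test_that("rejection draws always satisfy the area window", {
  isl <- random_islands(25, seed = 6)
  rng <- derive_area_range(isl, 2, 10)
  set.seed(1)
  for (i in 1:200) {
    pn <- sample(2:10, 1)
    idx <- sample_landscape(isl, pn, rng)
    expect_length(idx, pn)
    expect_false(anyDuplicated(idx) > 0)
    tot <- sum(isl$area_ha[idx])
    expect_gte(tot, rng[1]); expect_lte(tot, rng[2])
  }
  # an impossible window exhausts the budget
  expect_error(sample_landscape(isl, 2, c(1e6, 2e6), max_tries = 50),
               "exhausted")
})

test_that("constructive draws satisfy narrow windows rejection cannot reach", {
  isl <- random_islands(60, seed = 8)
  a <- isl$area_ha
  # window hugging the minimal total of 20 patches
  lo <- sum(sort(a)[1:20]); hi <- lo * 1.05
  set.seed(2)
  for (i in 1:50) {
    idx <- fragsar:::sample_landscape_guided(a, 20, lo, hi)
    expect_length(idx, 20)
    tot <- sum(a[idx])
    expect_gte(tot, lo); expect_lte(tot, hi)
  }
})

test_that("ensemble has the exact cell structure and section bounds", {
  isl <- random_islands(40, seed = 12)
  cfg <- sampler_config(pn_min = 2, pn_max = 12, n_sections = 3,
                        n_reps = 15)
  set.seed(3)
  ens <- build_ensemble(isl, cfg)
  L <- ens$landscapes
  expect_identical(nrow(L), 11L * 3L * 15L)
  expect_identical(length(ens$members), nrow(L))
  # every landscape sits inside its section and has the right size
  for (s in 1:3) {
    sel <- L$section == s
    expect_gte(min(L$area_total_ha[sel]), ens$breaks[s] - 1e-9)
    expect_lte(max(L$area_total_ha[sel]), ens$breaks[s + 1] + 1e-9)
  }
  expect_identical(L$pn, L$pn_level)
  expect_identical(lengths(ens$members), as.integer(L$pn_level))
  # per pn level, all sections occupied
  tab <- table(L$pn_level, L$section)
  expect_true(all(tab == 15L))
  # minimal configuration: counting
  set.seed(4)
  small <- build_ensemble(isl, sampler_config(2, 3, 1, 2))
  expect_identical(nrow(small$landscapes), 4L)
})

test_that("same seed reproduces the ensemble exactly", {
  isl <- random_islands(30, seed = 5)
  cfg <- sampler_config(2, 8, 2, 10)
  set.seed(99); e1 <- build_ensemble(isl, cfg)
  set.seed(99); e2 <- build_ensemble(isl, cfg)
  expect_identical(e1$members, e2$members)
  expect_identical(e1$landscapes, e2$landscapes)
})

test_that("pooled richness is bounded by member-island richness", {
  set.seed(14)
  arch <- generate_archipelago(synth_config(n_islands = 30, n_species = 50))
  cfg <- sampler_config(2, 10, 2, 10)
  set.seed(15)
  ens <- build_ensemble(arch, cfg)
  rich <- ensemble_richness(ens, arch)
  island_rich <- colSums(arch$incidence)
  for (i in seq_along(ens$members)) {
    mem <- ens$members[[i]]
    expect_gte(rich[i], max(island_rich[mem]))
    expect_lte(rich[i], min(nrow(arch$incidence), sum(island_rich[mem])))
  }
  # oracle: direct union count on a few landscapes
  for (i in sample(length(ens$members), 10)) {
    mem <- ens$members[[i]]
    expect_identical(
      rich[i],
      sum(rowSums(arch$incidence[, mem, drop = FALSE]) > 0))
  }
})

test_that("infeasible enumerated cells are detected", {
  # two big islands far from the rest: middle pair-sums unattainable
  isl <- data.frame(
    id = sprintf("g%02d", 1:20),
    area_ha = c(rep(0.5, 18), 100, 100),
    perimeter_m = fragsar:::circle_perimeter(c(rep(0.5, 18), 100, 100)) * 1.2,
    dist_mainland_m = 0)
  cfg <- sampler_config(2, 2, 5, 3, area_min = 1, area_max = 200)
  set.seed(1)
  expect_error(build_ensemble(isl, cfg), "no subset")
  expect_warning(ens <- build_ensemble(isl, cfg, on_infeasible = "skip"),
                 "no subset")
  expect_lt(nrow(ens$landscapes), 5 * 3)
})
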