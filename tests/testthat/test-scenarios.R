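test_that("scenario specifications encode the pleiotropy model", {
  s1 <- scenario_spec(1)
  expect_equal(s1$n_individuals, 200000)
  expect_length(s1$merges, 0)
  expect_equal(nrow(s1$map), 14)
  expect_equal(length(unique(s1$map$chrom)), 14)
  s2 <- scenario_spec(2)
  expect_equal(s2$n_individuals, 50000)
  expect_length(s2$merges, 2)
  expect_equal(length(unique(s2$map$chrom)), 12)   # two merged pairs
  expect_error(scenario_spec(3), "1 or 2")
})

test_that("DH class frequencies are uniform over a down-scaled panel", {
  # 6 unlinked loci: 64 classes, each with probability 2^-6
  map <- toy_map(6)
  cr <- toy_cross(map)
  set.seed(61)
  pop <- make_dh(expand_plant(cr$f1, 32000))
  cf <- genotype_class_frequencies(pop)
  expect_equal(sum(cf$frequency), 100)
  expect_equal(nrow(cf), 64)
  expect_gt(stats::chisq.test(cf$count)$p.value, 0.001)
})

test_that("merged pairs never recombine in scenario 2", {
  s2 <- scenario_spec(2, n_individuals = 20000)
  set.seed(62)
  sdh <- simulate_sdh_population(s2)
  g <- genotype_codes(sdh$pop)
  for (m in s2$merges)
    expect_true(all(g[, m[1]] == g[, m[2]]))
  # and per-class frequencies cluster around 2^-12 over the 4096 classes
  expect_lte(nrow(sdh$class_freq), 4096)
})

test_that("one-locus toy scenario splits into two equal classes", {
  map <- toy_map(1)
  cr <- toy_cross(map)
  set.seed(63)
  pop <- make_dh(expand_plant(cr$f1, 10000))
  cf <- genotype_class_frequencies(pop)
  expect_equal(nrow(cf), 2)
  expect_true(all(abs(cf$frequency - 50) < 3 * 100 * sqrt(0.25 / 10000)))
})

test_that("yield categories expose the pleiotropy constraint on height", {
  n <- 20000
  s1 <- scenario_spec(1, n_individuals = n)
  s2 <- scenario_spec(2, n_individuals = n)
  set.seed(64)
  pop1 <- simulate_sdh_population(s1)$pop
  pop2 <- simulate_sdh_population(s2)$pop
  c1 <- classify_by_yield(pop1, s1$effects)
  c2 <- classify_by_yield(pop2, s2$effects)
  top1 <- c1$assignment == max(c1$assignment)
  top2 <- c2$assignment == max(c2$assignment)
  ph2d_1 <- genotype_codes(pop1)[, "qPH-psr-2D"]
  ph2d_2 <- genotype_codes(pop2)[, "qPH-psr-2D"]
  # scenario 1: short (2D height-decreasing) lines do reach the top yield bin
  expect_gt(sum(ph2d_1 == "AA" & top1), 0)
  # scenario 2: the 2D yield/height unit forces all top-yield lines tall
  expect_equal(sum(ph2d_2 == "AA" & top2), 0)
  expect_gt(min(c2$summary$ph_min[nrow(c2$summary)]),
            min(c2$summary$ph_min))
})

test_that("degenerate yield classification collapses to one category", {
  map <- toy_map(1)
  pop <- inbred_line("C", map)
  pop5 <- bind_populations(pop, pop, pop, pop, pop)
  eff <- toy_effects("L1", 0.3)
  out <- classify_by_yield(pop5, eff)
  expect_equal(unique(out$assignment), 1L)
  expect_equal(nrow(out$summary), 1)
})

test_that("single-locus yield split gives two disjoint categories", {
  map <- toy_map(1)
  cr <- toy_cross(map)
  set.seed(65)
  pop <- make_dh(expand_plant(cr$f1, 2000))
  eff <- rbind(toy_effects("L1", 0.3),
               toy_effects("L1", 2, trait = "PH"),
               toy_effects("L1", 1, trait = "EM"))
  out <- classify_by_yield(pop, eff, n_categories = 2)
  expect_equal(nrow(out$summary), 2)
  expect_lt(out$summary$gy_max[1], out$summary$gy_min[2])
})

test_that("ideal genotype attainability follows the merge rule", {
  ideals <- ideal_sdh_genotypes()
  expect_equal(dim(ideals), c(14, 9))
  expect_true(all(ideals %in% c("A", "C")))
  a1 <- attainable_ideal_genotypes(ideals, scenario_spec(1))
  expect_equal(sum(a1), 9)
  a2 <- attainable_ideal_genotypes(ideals, scenario_spec(2))
  expect_equal(sum(a2), 6)
  expect_identical(names(which(!a2)), c("SDH2", "SDH5", "SDH8"))
  empty <- ideals[, 0, drop = FALSE]
  expect_length(attainable_ideal_genotypes(empty, scenario_spec(2)), 0)
})
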