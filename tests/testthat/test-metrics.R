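test_that("extreme target values span the additive range", {
  eff1 <- toy_effects("L1", 0.4)
  expect_equal(extreme_target_values(eff1, "GY"),
               c(tg_l = -0.4, tg_h = 0.4))
  expect_equal(extreme_target_values(eff1, "GY", baseline = 7),
               c(tg_l = 6.6, tg_h = 7.4))
  eff3 <- toy_effects(c("L1", "L2", "L3"), c(0.3, 0.2, 0.1),
                      parent = c("C", "A", "C"))
  tg <- extreme_target_values(eff3, "GY")
  expect_equal(unname(tg["tg_h"] - tg["tg_l"]), 2 * (0.3 + 0.2 + 0.1))
  expect_error(extreme_target_values(eff3, "PH"), "no effect loci")
})

test_that("the best extreme can match neither parent when signs mix", {
  fx <- avalon_cadenza_fixture()
  tg <- extreme_target_values(fx$effects, "GY")
  for (p in c("Avalon", "Cadenza")) {
    v <- genotypic_value(fx$parents[[p]], fx$effects, "GY")
    expect_lt(v, tg["tg_h"])
    expect_gt(v, tg["tg_l"])
  }
})

test_that("adjusted fitness is a 0-100 rescaling with the right anchors", {
  expect_equal(adjusted_fitness(1, -1, 1), 100)   # fixed at best extreme
  expect_equal(adjusted_fitness(-1, -1, 1), 0)    # fixed at worst extreme
  expect_equal(adjusted_fitness(0, -1, 1), 50)    # F1: zero net contribution
  expect_error(adjusted_fitness(0, 1, 1), "greater")
})

test_that("adjusted fitness is invariant under affine rescaling of effects", {
  map <- toy_map(4)
  eff <- toy_effects(paste0("L", 1:4), c(0.3, 0.1, 0.2, 0.05),
                     parent = c("C", "A", "C", "C"))
  cr <- toy_cross(map)
  set.seed(12)
  pop <- make_dh(expand_plant(cr$f1, 300))
  fad <- function(effects, baseline) {
    tg <- extreme_target_values(effects, "GY", baseline = baseline)
    adjusted_fitness(mean(genotypic_value(pop, effects, "GY", baseline = baseline)),
                     tg["tg_l"], tg["tg_h"])
  }
  eff_scaled <- eff
  eff_scaled$additive_effect <- eff$additive_effect * 3.7
  expect_equal(fad(eff, 0), fad(eff_scaled, 12.5))
})

test_that("adding an above-average target line never lowers adjusted fitness", {
  vals <- c(0.1, -0.2, 0.05)
  tg_l <- -1; tg_h <- 1
  before <- adjusted_fitness(mean(vals), tg_l, tg_h)
  after <- adjusted_fitness(mean(c(vals, 0.9)), tg_l, tg_h)
  expect_gte(after, before)
})

test_that("gain per year divides the cycle gain by the cycle length", {
  expect_equal(years_per_cycle("F2DH"), 2L)
  expect_equal(years_per_cycle("RIL"), 3L)
  expect_equal(years_per_cycle("MSSD"), 3L)
  # assemble a minimal summary by hand: before at F_ad 50, after at 100
  eff <- toy_effects("L1", 0.5)
  reps <- data.frame(rep = 1:2, retained_f2 = 1, final_size = 1,
                     n_targets = 1, f_before = 0, f_after = 0.5)
  for (strat in c("F2DH", "RIL")) {
    summ <- structure(list(strategy = strat, reps = reps),
                      class = "strategy_summary")
    g <- genetic_gain(summ, eff)
    expect_equal(g$f_ad_before, 50)
    expect_equal(g$f_ad_after, 100)
    expect_equal(g$gain_per_cycle, 50)
    expect_equal(g$gain_per_year, 50 / years_per_cycle(strat))
  }
  # unchanged population: zero gain; zero-target replicates contribute zero
  reps0 <- data.frame(rep = 1, retained_f2 = 1, final_size = 1,
                      n_targets = 0, f_before = 0.1, f_after = NA_real_)
  summ0 <- structure(list(strategy = "F2DH", reps = reps0),
                     class = "strategy_summary")
  expect_equal(genetic_gain(summ0, eff)$gain_per_cycle, 0)
})

test_that("closed-form expectations reproduce their anchors", {
  e <- analytic_expectations("F2DH", k = 13, n = 2000)
  expect_equal(unname(e["retained"]), 2000 * 0.75^13)
  expect_equal(unname(e["retained"]), 47.51, tolerance = 1e-3)
  expect_equal(unname(e["targets"]), 2000 * (2 / 3)^13)
  expect_equal(unname(e["targets"]), 10.28, tolerance = 1e-3)
  e16 <- analytic_expectations("RIL", k = 16, n = 5000)
  expect_equal(unname(e16["retained"]), 50.11, tolerance = 1e-3)
  expect_equal(unname(e16["targets"]), 5000 * (31 / 48)^16)
  e0 <- analytic_expectations("MSSD", k = 0, n = 700)
  expect_equal(unname(e0), c(700, 700))
})
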