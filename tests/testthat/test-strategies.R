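test_that("enrichment keeps exactly the plants that can still reach the target", {
  map <- toy_map(2)
  tgt <- target_genotype(c("L1", "L2"), c("A", "C"))
  codes <- matrix(c("AC", "AC",    # heterozygous everywhere: kept
                    "CC", "CC",    # homozygous non-target at L1: discarded
                    "AA", "CC",    # target homozygote: kept
                    "AA", "AA"),   # homozygous non-target at L2: discarded
                  4, 2, byrow = TRUE, dimnames = list(NULL, map$locus))
  pop <- population_from_codes(codes, map)
  keep <- f2_enrichment_keep(pop, tgt, c("L1", "L2"))
  expect_identical(keep, c(TRUE, FALSE, TRUE, FALSE))
  # discarded plants have target probability exactly zero; retained do not
  tm <- genotype_codes(pop)
  can_reach <- apply(tm, 1, function(g)
    sum(strsplit(g[1], "")[[1]] == "A") > 0 && sum(strsplit(g[2], "")[[1]] == "C") > 0)
  expect_identical(keep, unname(can_reach))
  # an empty retained set is a valid outcome, not an error
  all_bad <- population_from_codes(matrix(c("CC", "AA"), 1, 2,
    dimnames = list(NULL, map$locus)), map)
  expect_identical(f2_enrichment_keep(all_bad, tgt, c("L1", "L2")), FALSE)
  expect_equal(n_plants(f2_enrichment_select(all_bad, tgt, c("L1", "L2"))), 0)
})

test_that("enrichment retention matches (3/4)^k for independent loci", {
  k <- 5
  cr <- toy_cross(toy_map(k))
  tgt <- target_genotype(paste0("L", 1:k), rep(c("A", "C"), length.out = k))
  set.seed(99)
  n <- 20000
  f2 <- make_f2(cr$f1, n)
  keep <- f2_enrichment_keep(f2, tgt)
  p <- 0.75^k
  expect_lt(abs(mean(keep) - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("counting targets agrees with a brute-force oracle", {
  map <- toy_map(2)
  tgt <- target_genotype(c("L1", "L2"), c("C", "A"))
  cr <- toy_cross(map)
  set.seed(3)
  dh <- make_dh(expand_plant(cr$f1, 500))
  brute <- sum(apply(genotype_codes(dh), 1,
                     function(g) g[1] == "CC" && g[2] == "AA"))
  expect_equal(count_targets(dh, tgt), brute)
  # heterozygotes never count
  f1s <- expand_plant(cr$f1, 10)
  expect_equal(count_targets(f1s, tgt), 0)
})

test_that("none of the panel parents is itself the target genotype", {
  fx <- avalon_cadenza_fixture()
  for (nm in c("DH27", "DH61", "DH182", "DH109", "DH160"))
    expect_equal(count_targets(fx$parents[[nm]], fx$target), 0)
})

test_that("degenerate strategy runs behave sensibly", {
  # identical parents, target = parent genotype: every line is a target
  map <- toy_map(3)
  p <- inbred_line(c("A", "C", "A"), map)
  tgt <- target_genotype(map$locus, c("A", "C", "A"))
  set.seed(8)
  run <- run_f2_dh(p, p, tgt, f2_size = 50, final_size = 40)
  expect_equal(run$retained_f2, 50)   # nothing segregates, all retained
  expect_equal(run$n_targets, 40)
  run_r <- run_ril(p, p, tgt, f2_size = 30, final_size = 25)
  expect_equal(run_r$n_targets, 25)
  # a replicate with zero retained F2 plants records zero targets
  fx <- avalon_cadenza_fixture()
  got_zero <- FALSE
  for (s in 1:6) {
    set.seed(s)
    r <- run_f2_dh(fx$parents$DH61, fx$parents$DH182, fx$target, f2_size = 1)
    expect_true(r$retained_f2 %in% c(0L, 1L))
    if (r$retained_f2 == 0L) {
      got_zero <- TRUE
      expect_equal(r$n_targets, 0L)
      expect_equal(r$final_size, 0L)
    }
  }
  expect_true(got_zero)
})

test_that("single-locus strategy probabilities match selfing algebra", {
  map <- toy_map(1)
  cr <- toy_cross(map)
  tgt <- target_genotype("L1", "C")
  # F2-DH after enrichment: target fraction 1/3 * 1 + 2/3 * 1/2 = 2/3
  set.seed(21)
  s <- simulate_strategy("F2DH", cr$p1, cr$p2, tgt, f2_size = 400,
                         final_size = 400, n_reps = 60, seed = 21)
  p_hat <- s$n_targets_mean / 400
  expect_lt(abs(p_hat - 2 / 3), 3 * sd(s$reps$n_targets / 400) / sqrt(60))
  # RIL at F6: 1/3 + (2/3) * (15/32) = 31/48 (four selfing steps F2 -> F6)
  s2 <- simulate_strategy("RIL", cr$p1, cr$p2, tgt, f2_size = 400,
                          final_size = 400, n_reps = 60, seed = 22)
  p2_hat <- s2$n_targets_mean / 400
  expect_lt(abs(p2_hat - 31 / 48), 3 * sd(s2$reps$n_targets / 400) / sqrt(60))
})

test_that("strategy ranking holds under common settings", {
  k <- 5
  cr <- toy_cross(toy_map(k))
  tgt <- target_genotype(paste0("L", 1:k), rep(c("A", "C"), length.out = k))
  n <- 600
  f2dh <- simulate_strategy("F2DH", cr$p1, cr$p2, tgt, n, n, n_reps = 40, seed = 31)
  ril <- simulate_strategy("RIL", cr$p1, cr$p2, tgt, n, n, n_reps = 40, seed = 32)
  mssd <- simulate_strategy("MSSD", cr$p1, cr$p2, tgt, f2_size = n,
                            n_reps = 40, seed = 33)
  # F2-DH beats RIL decisively ((2/3)^k vs (31/48)^k per line)
  expect_gt(f2dh$n_targets_mean, ril$n_targets_mean)
  # RIL at least matches modified SSD per unit of census
  ril_rate <- ril$n_targets_mean / n
  mssd_rate <- mssd$n_targets_mean / mean(3 * mssd$reps$retained_f2)
  expect_gt(ril_rate, mssd_rate - 3 * stats::sd(mssd$reps$n_targets /
              (3 * mssd$reps$retained_f2)) / sqrt(40))
})

test_that("modified SSD holds its census at three seeds per retained plant", {
  fx <- avalon_cadenza_fixture()
  set.seed(44)
  r <- run_modified_ssd(fx$parents$DH61, fx$parents$DH182, fx$target,
                        f2_size = 2000)
  expect_equal(r$final_size, 3 * r$retained_f2)
})

test_that("replicate streams are deterministic and reproducible", {
  map <- toy_map(3)
  cr <- toy_cross(map)
  tgt <- target_genotype(map$locus, c("A", "C", "C"))
  a <- simulate_strategy("F2DH", cr$p1, cr$p2, tgt, 100, 100, n_reps = 5, seed = 7)
  b <- simulate_strategy("F2DH", cr$p1, cr$p2, tgt, 100, 100, n_reps = 5, seed = 7)
  expect_identical(a$reps, b$reps)
  c2 <- simulate_strategy("F2DH", cr$p1, cr$p2, tgt, 100, 100, n_reps = 5, seed = 8)
  expect_false(identical(a$reps, c2$reps))
  expect_identical(derive_seed(7, 3), derive_seed(7, 3))
  expect_lt(derive_seed(2^31 - 2, 10^6), 2^31)
})
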