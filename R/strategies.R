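#' Target genotypes and marker-assisted selection
#'
#' A target genotype is a named character vector mapping locus ids to the
#' parental-origin allele (`"A"` or `"C"`) required in homozygous state.
#'
#' @param locus Character vector of locus ids.
#' @param origin Character vector of required allele origins (`"A"`/`"C"`).
#' @return Named character vector of class `target_genotype`.
#' @export
target_genotype <- function(locus, origin) {
  if (length(locus) != length(origin)) stop("locus and origin must match in length")
  if (!all(origin %in% c("A", "C"))) stop("allele origins must be 'A' or 'C'")
  if (anyDuplicated(locus)) stop("duplicate loci in target genotype")
  structure(stats::setNames(as.character(origin), locus),
            class = "target_genotype")
}

#' Loci segregating between two homozygous parents
#'
#' @param p1,p2 Single-plant homozygous `line_population` objects.
#' @param target Optional `target_genotype`; if given, only target loci are
#'   considered.
#' @return Character vector of locus ids at which the parents differ.
#' @export
segregating_loci <- function(p1, p2, target = NULL) {
  if (!identical(p1$map$locus, p2$map$locus)) stop("parents must share a map")
  seg <- p1$map$locus[as.vector(p1$hap1[1, ] != p2$hap1[1, ])]
  if (!is.null(target)) seg <- intersect(seg, names(target))
  seg
}

target_matrix <- function(pop, target, loci) {
  j <- match(loci, pop$map$locus)
  if (anyNA(j)) stop("target loci absent from map: ",
                     paste(loci[is.na(j)], collapse = ", "))
  t_allele <- as.integer(unclass(target)[loci] == "C")
  list(j = j, t = matrix(t_allele, n_plants(pop), length(j), byrow = TRUE))
}

#' F2 enrichment by marker-assisted selection
#'
#' Keeps exactly those plants carrying at least one copy of the required
#' target allele at every segregating target locus; any plant homozygous
#' for the non-target allele at any such locus is discarded. Retained
#' plants can still yield the target genotype by selfing or DH induction;
#' discarded plants have target probability exactly zero.
#'
#' @param pop A `line_population` (typically an F2).
#' @param target A `target_genotype`.
#' @param loci Loci to select on; defaults to the target loci that are
#'   polymorphic in `pop` (fixed loci are ignored).
#' @return Logical vector marking the retained plants. An all-`FALSE`
#'   result is a valid outcome.
#' @export
f2_enrichment_keep <- function(pop, target, loci = NULL) {
  if (is.null(loci)) {
    cand <- intersect(names(target), pop$map$locus)
    j <- match(cand, pop$map$locus)
    poly <- vapply(j, function(k) {
      a <- c(pop$hap1[, k], pop$hap2[, k]); any(a != a[1])
    }, logical(1))
    loci <- cand[poly]
  }
  if (length(loci) == 0) return(rep(TRUE, n_plants(pop)))
  tm <- target_matrix(pop, target, loci)
  has <- (pop$hap1[, tm$j, drop = FALSE] == tm$t) |
         (pop$hap2[, tm$j, drop = FALSE] == tm$t)
  rowSums(has) == length(loci)
}

#' @rdname f2_enrichment_keep
#' @return `f2_enrichment_select` returns the retained sub-population.
#' @export
f2_enrichment_select <- function(pop, target, loci = NULL) {
  subset_plants(pop, f2_enrichment_keep(pop, target, loci))
}

#' Count target genotypes in a population
#'
#' A plant counts as a target genotype only when homozygous for the
#' required allele at every target locus; heterozygotes never count.
#'
#' @param pop A `line_population`.
#' @param target A `target_genotype`.
#' @return Integer count.
#' @export
count_targets <- function(pop, target) sum(is_target(pop, target))

#' @rdname count_targets
#' @return `is_target` returns a logical vector over plants.
#' @export
is_target <- function(pop, target) {
  loci <- names(target)
  tm <- target_matrix(pop, target, loci)
  hit <- (pop$hap1[, tm$j, drop = FALSE] == tm$t) &
         (pop$hap2[, tm$j, drop = FALSE] == tm$t)
  rowSums(hit) == length(loci)
}

strategy_run <- function(strategy, retained_f2, final_pop, target,
                         f2_gy = NA_real_, effects = NULL, gy_envs = "MET",
                         keep_pop = FALSE) {
  n_final <- n_plants(final_pop)
  tgt <- is_target(final_pop, target)
  f_after <- NA_real_
  if (!is.null(effects) && any(tgt))
    f_after <- mean(genotypic_value(subset_plants(final_pop, tgt), effects,
                                    "GY", gy_envs))
  structure(list(strategy = strategy, retained_f2 = retained_f2,
                 final_size = n_final, n_targets = sum(tgt),
                 f_before = f2_gy, f_after = f_after,
                 final_population = if (keep_pop) final_pop else NULL),
            class = "strategy_run")
}

#' @export
print.strategy_run <- function(x, ...) {
  cat(sprintf("%s run: retained F2 = %d, final population = %d, targets = %d\n",
              x$strategy, x$retained_f2, x$final_size, x$n_targets))
  invisible(x)
}

empty_run <- function(strategy, retained, map) {
  ep <- line_population(matrix(integer(), 0, nrow(map)),
                        matrix(integer(), 0, nrow(map)), map)
  structure(list(strategy = strategy, retained_f2 = retained, final_size = 0L,
                 n_targets = 0L, f_before = NA_real_, f_after = NA_real_,
                 final_population = ep),
            class = "strategy_run")
}

f2_and_enrich <- function(p1, p2, target, f2_size, effects, gy_envs) {
  f1 <- make_f1(p1, p2)
  f2 <- make_f2(f1, f2_size)
  f2_gy <- if (!is.null(effects))
    mean(genotypic_value(f2, effects, "GY", gy_envs)) else NA_real_
  seg <- segregating_loci(p1, p2, target)
  keep <- f2_enrichment_keep(f2, target, seg)
  list(f2 = f2, keep = keep, f2_gy = f2_gy)
}

#' The F2-DH breeding strategy
#'
#' One cycle of the F2-DH strategy: F1 from two homozygous parents, an F2
#' of `f2_size`, F2 enrichment by MAS at the segregating target loci, then
#' `final_size` doubled-haploid lines produced from the retained plants
#' (allocated round-robin so plants contribute near-equally), and final
#' MAS for the homozygous target genotype.
#'
#' @param p1,p2 Homozygous parents (single-plant `line_population`s).
#' @param target A `target_genotype`.
#' @param f2_size F2 population size before enrichment.
#' @param final_size DH population size before final selection.
#' @param effects Optional effect table; if given, mean GY genotypic values
#'   of the F2 (before selection) and of the selected target lines are
#'   recorded for genetic-gain computation.
#' @param gy_envs Environment label(s) used for the GY genotypic value.
#' @param keep_pop Keep the final population in the result?
#' @return A `strategy_run` with elements `retained_f2`, `final_size`,
#'   `n_targets`, `f_before`, `f_after`.
#' @export
run_f2_dh <- function(p1, p2, target, f2_size, final_size = f2_size,
                      effects = NULL, gy_envs = "MET", keep_pop = FALSE) {
  st <- f2_and_enrich(p1, p2, target, f2_size, effects, gy_envs)
  k <- sum(st$keep)
  if (k == 0) return(empty_run("F2DH", 0L, p1$map))
  kept <- subset_plants(st$f2, st$keep)
  dh <- make_dh(kept, rep_len(seq_len(k), final_size))
  strategy_run("F2DH", k, dh, target, st$f2_gy, effects, gy_envs, keep_pop)
}

#' The RIL (bulk selfing) breeding strategy
#'
#' F2 enrichment, then bulk selfing from F3 to F6: each generation is a
#' population of `final_size` plants, every plant a self-seed of a random
#' plant of the previous generation (retained F2 plants contribute to the
#' F3 round-robin, i.e. near-equally). Final MAS at F6.
#'
#' @inheritParams run_f2_dh
#' @return A `strategy_run`.
#' @export
run_ril <- function(p1, p2, target, f2_size, final_size = f2_size,
                    effects = NULL, gy_envs = "MET", keep_pop = FALSE) {
  st <- f2_and_enrich(p1, p2, target, f2_size, effects, gy_envs)
  k <- sum(st$keep)
  if (k == 0) return(empty_run("RIL", 0L, p1$map))
  gen <- self_plants(subset_plants(st$f2, st$keep),
                     rep_len(seq_len(k), final_size))        # F3
  for (g in 1:3)                                             # F4, F5, F6
    gen <- self_plants(gen, sample.int(final_size, final_size, replace = TRUE))
  strategy_run("RIL", k, gen, target, st$f2_gy, effects, gy_envs, keep_pop)
}

#' The modified single-seed-descent strategy
#'
#' Pedigree-tracked F2 enrichment on a large F2; each retained plant
#' contributes `seeds_per_plant` self-seeds to the F3; from F4 to F6 every
#' plant again sets `seeds_per_plant` seeds, and the bulked seed lot is
#' sampled without replacement back to the F3 census size. Final MAS at F6.
#'
#' @inheritParams run_f2_dh
#' @param seeds_per_plant Self-seeds harvested per plant (default 3).
#' @return A `strategy_run`.
#' @export
run_modified_ssd <- function(p1, p2, target, f2_size, seeds_per_plant = 3,
                             effects = NULL, gy_envs = "MET", keep_pop = FALSE) {
  st <- f2_and_enrich(p1, p2, target, f2_size, effects, gy_envs)
  k <- sum(st$keep)
  if (k == 0) return(empty_run("MSSD", 0L, p1$map))
  census <- k * seeds_per_plant
  gen <- self_plants(subset_plants(st$f2, st$keep),
                     rep(seq_len(k), each = seeds_per_plant))   # F3
  for (g in 1:3) {                                              # F4, F5, F6
    pool <- rep(seq_len(census), each = seeds_per_plant)
    gen <- self_plants(gen, sample(pool, census))
  }
  strategy_run("MSSD", k, gen, target, st$f2_gy, effects, gy_envs, keep_pop)
}

#' Replicate F2 enrichment alone
#'
#' Simulates only the F2-and-enrichment stage of a strategy (no inbred or
#' DH line development) for `n_reps` replicates, reporting the retained
#' population sizes. Useful for studying the population-size reduction of
#' marker-assisted F2 enrichment by itself.
#'
#' @inheritParams simulate_strategy
#' @return List with `retained` (integer vector over replicates),
#'   `retained_mean` and `retained_se`.
#' @export
simulate_enrichment <- function(p1, p2, target, f2_size, n_reps = 1000,
                                seed = 1) {
  f1 <- make_f1(p1, p2)
  seg <- segregating_loci(p1, p2, target)
  retained <- integer(n_reps)
  for (i in seq_len(n_reps)) {
    set.seed(derive_seed(seed, i))
    f2 <- make_f2(f1, f2_size)
    retained[i] <- sum(f2_enrichment_keep(f2, target, seg))
  }
  list(retained = retained, retained_mean = mean(retained),
       retained_se = if (n_reps > 1) stats::sd(retained) / sqrt(n_reps) else NA_real_)
}

#' Derive a reproducible per-replicate seed
#'
#' Deterministically maps a master seed and a replicate index to a seed
#' below 2^31, so any replicate can be reproduced in isolation.
#'
#' @param master Master seed (integer).
#' @param index Replicate index (1-based integer).
#' @return Integer seed.
#' @export
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) %% 2147483647 * 10007 + as.numeric(index)) %%
               2147483647)
}

#' Replicate a breeding strategy
#'
#' Runs one breeding strategy for `n_reps` independent replicates, seeding
#' each replicate from `derive_seed(seed, rep)`, and summarises retained
#' F2 counts, target-genotype counts and (when an effect table is given)
#' genetic gain on the adjusted-fitness scale.
#'
#' @param strategy One of `"F2DH"`, `"RIL"`, `"MSSD"`.
#' @inheritParams run_f2_dh
#' @param n_reps Number of replicate runs.
#' @param seed Master seed; every source of randomness derives from it.
#' @param seeds_per_plant Seeds per plant for the modified SSD strategy.
#' @return Object of class `strategy_summary`: a list with `reps` (one row
#'   per replicate: `retained_f2`, `n_targets`, `f_before`, `f_after`) and
#'   summary statistics (means and standard errors).
#' @export
simulate_strategy <- function(strategy = c("F2DH", "RIL", "MSSD"),
                              p1, p2, target, f2_size, final_size = f2_size,
                              n_reps = 1000, seed = 1, effects = NULL,
                              gy_envs = "MET", seeds_per_plant = 3) {
  strategy <- match.arg(strategy)
  runner <- switch(strategy,
    F2DH = function() run_f2_dh(p1, p2, target, f2_size, final_size, effects, gy_envs),
    RIL  = function() run_ril(p1, p2, target, f2_size, final_size, effects, gy_envs),
    MSSD = function() run_modified_ssd(p1, p2, target, f2_size, seeds_per_plant,
                                       effects, gy_envs))
  reps <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    set.seed(derive_seed(seed, i))
    r <- runner()
    reps[[i]] <- data.frame(rep = i, retained_f2 = r$retained_f2,
                            final_size = r$final_size, n_targets = r$n_targets,
                            f_before = r$f_before, f_after = r$f_after)
  }
  reps <- do.call(rbind, reps)
  se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  structure(list(strategy = strategy, n_reps = n_reps, seed = seed,
                 f2_size = f2_size, final_size = final_size,
                 reps = reps,
                 retained_mean = mean(reps$retained_f2),
                 retained_se = se(reps$retained_f2),
                 n_targets_mean = mean(reps$n_targets),
                 n_targets_se = se(reps$n_targets)),
            class = "strategy_summary")
}

#' @export
print.strategy_summary <- function(x, ...) {
  cat(sprintf("%s: %d replicates, F2 size %d\n", x$strategy, x$n_reps, x$f2_size))
  cat(sprintf("  retained F2: %.2f +/- %.3f\n", x$retained_mean,
              x$retained_se))
  cat(sprintf("  target genotypes: %.3f +/- %.3f\n", x$n_targets_mean,
              x$n_targets_se))
  invisible(x)
}
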