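#' Genotypic values of the two extreme target genotypes
#'
#' `TG_h` is the genotypic value of a line fixed for the increasing allele
#' at every locus with an effect on the trait; `TG_l` fixes the decreasing
#' allele everywhere. Effects are averaged per locus over the requested
#' environments.
#'
#' @param effects Effect table (`locus_id`, `trait`, `environment`,
#'   `additive_effect`, `increasing_parent`).
#' @param trait Trait label.
#' @param environments Environment label(s); multiple labels are averaged.
#' @param baseline Zero point (default 0, the midparent scale).
#' @return Named numeric vector `c(tg_l = ..., tg_h = ...)`.
#' @export
extreme_target_values <- function(effects, trait, environments = "MET",
                                  baseline = 0) {
  rows <- effects[effects$trait == trait &
                    effects$environment %in% environments, , drop = FALSE]
  if (nrow(rows) == 0) stop("no effect loci for trait '", trait, "'")
  per_locus <- tapply(rows$additive_effect, rows$locus_id, mean)
  span <- sum(abs(per_locus))
  c(tg_l = baseline - span, tg_h = baseline + span)
}

#' Adjusted fitness
#'
#' Rescales a population mean genotypic value linearly so that a
#' population fixed for the worst extreme target genotype scores 0 and one
#' fixed for the best scores 100:
#' `F_ad = 100 * (F - TG_l) / (TG_h - TG_l)`.
#'
#' @param f Population mean genotypic value(s) (numeric vector).
#' @param tg_l,tg_h Genotypic values of the two extreme target genotypes;
#'   `tg_h` must exceed `tg_l`.
#' @return Adjusted fitness on the 0-100 scale.
#' @export
adjusted_fitness <- function(f, tg_l, tg_h) {
  if (!is.finite(tg_l) || !is.finite(tg_h) || tg_h <= tg_l)
    stop("tg_h must be greater than tg_l")
  100 * (f - tg_l) / (tg_h - tg_l)
}

#' Years per breeding cycle
#'
#' The F2-DH strategy completes a cycle in 2 years (doubled haploids are
#' produced in one year and two glasshouse generations fit in a year); the
#' RIL and modified SSD strategies need 3 years to reach F6.
#'
#' @param strategy `"F2DH"`, `"RIL"` or `"MSSD"`.
#' @return Integer number of years.
#' @export
years_per_cycle <- function(strategy) {
  switch(match.arg(strategy, c("F2DH", "RIL", "MSSD")), F2DH = 2L, 3L)
}

#' Genetic gain of a breeding cycle
#'
#' Gain per cycle is the difference in GY adjusted fitness between the
#' population before the cycle (the F2 before any selection) and the
#' selected target lines at the end of the cycle; gain per year divides by
#' the cycle length. Replicates that recover no target line leave the
#' population unchanged and contribute a gain of 0.
#'
#' @param summary A `strategy_summary` from [simulate_strategy()] run with
#'   an effect table (so `f_before`/`f_after` are populated).
#' @param effects Effect table used to compute the extreme target values.
#' @param gy_envs Environment label(s) for the GY effects.
#' @param baseline Baseline genotypic value.
#' @return Object of class `gain_report`: means over replicates of
#'   adjusted fitness before and after, gain per cycle and per year.
#' @export
genetic_gain <- function(summary, effects, gy_envs = "MET", baseline = 0) {
  tg <- extreme_target_values(effects, "GY", gy_envs, baseline)
  reps <- summary$reps
  if (all(is.na(reps$f_before)))
    stop("strategy was simulated without an effect table; no fitness recorded")
  fad_before <- adjusted_fitness(reps$f_before, tg["tg_l"], tg["tg_h"])
  fad_after <- ifelse(is.na(reps$f_after), fad_before,
                      adjusted_fitness(reps$f_after, tg["tg_l"], tg["tg_h"]))
  gain_cycle <- fad_after - fad_before
  yrs <- years_per_cycle(summary$strategy)
  structure(list(strategy = summary$strategy,
                 tg_l = unname(tg["tg_l"]), tg_h = unname(tg["tg_h"]),
                 f_ad_before = mean(fad_before), f_ad_after = mean(fad_after),
                 gain_per_cycle = mean(gain_cycle),
                 years_per_cycle = yrs,
                 gain_per_year = mean(gain_cycle) / yrs),
            class = "gain_report")
}

#' @export
print.gain_report <- function(x, ...) {
  cat(sprintf("%s gain: F_ad %.2f -> %.2f; per cycle %.2f, per year %.2f (%d yr/cycle)\n",
              x$strategy, x$f_ad_before, x$f_ad_after, x$gain_per_cycle,
              x$gain_per_year, x$years_per_cycle))
  invisible(x)
}

#' Closed-form expectations under independent segregation
#'
#' For `k` independently segregating target loci and census size `n`:
#' enrichment retains `n * (3/4)^k` plants in expectation (each F2 plant
#' carries the target allele at a locus with probability 3/4); a DH line
#' made from a retained plant is a full target with probability `(2/3)^k`
#' (per locus, 1/3 of retained plants are fixed and 2/3 heterozygous, the
#' latter transmitting the target allele with probability 1/2); and an F6
#' plant descending from a retained F2 plant by four rounds of selfing is
#' a full target with probability `(31/48)^k` (the heterozygous fraction
#' halves each generation, leaving `15/32` target homozygotes after four
#' selfings, so per locus `1/3 + 2/3 * 15/32`).
#'
#' @param strategy `"F2DH"`, `"RIL"` or `"MSSD"`.
#' @param k Number of independently segregating target loci.
#' @param n Census size (F2 size for `retained`, final population size for
#'   `targets`).
#' @return Named numeric vector `c(retained = ..., targets = ...)` where
#'   `retained` uses the F2 size and `targets` the final census.
#' @export
analytic_expectations <- function(strategy = c("F2DH", "RIL", "MSSD"), k, n,
                                  final_n = n) {
  strategy <- match.arg(strategy)
  stopifnot(k >= 0, n >= 1)
  p_target <- if (strategy == "F2DH") (2 / 3)^k else (31 / 48)^k
  c(retained = n * 0.75^k, targets = final_n * p_target)
}
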