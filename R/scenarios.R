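#' Scenario specification for simulated DH populations
#'
#' Defines the 14-locus yield/height/ear-emergence panel used to generate
#' large simulated doubled-haploid (SDH) populations from the
#' Avalon x Cadenza F1. Under scenario 1 all 14 loci segregate
#' independently; under scenario 2 the two co-located pairs — the 2D
#' yield/height pair and the 3A height/ear-emergence pair — are treated
#' as single pleiotropic inheritance units (complete linkage), leaving 12
#' independent units. Partial linkage can be explored by editing the
#' returned map, but complete linkage is the default reading of
#' pleiotropy.
#'
#' @param scenario 1 or 2.
#' @param n_individuals SDH population size; defaults to 200,000 for
#'   scenario 1 and 50,000 for scenario 2.
#' @return List of class `scenario_spec` with `scenario`, `n_individuals`,
#'   `map` (a `linkage_map` over the 14 loci), `merges` (list of linked
#'   locus pairs), and `effects` (per-trait, per-environment additive
#'   effects for the panel).
#' @export
scenario_spec <- function(scenario = 1,
                          n_individuals = if (scenario == 1) 200000 else 50000) {
  if (!scenario %in% c(1, 2)) stop("scenario must be 1 or 2")
  path <- system.file("extdata", "scenario_effects.tsv", package = "breedsimr",
                      mustWork = TRUE)
  effects <- utils::read.delim(path, stringsAsFactors = FALSE)
  loci <- scenario_loci()
  merges <- list(c("qGY-psr-2D.1", "qPH-psr-2D"),
                 c("qPH-psr-3A", "qEM-psr-3A"))
  if (scenario == 1) {
    map <- linkage_map(loci, paste0("u_", seq_along(loci)), rep(0, length(loci)))
  } else {
    chrom <- paste0("u_", seq_along(loci))
    names(chrom) <- loci
    for (m in merges) chrom[m] <- chrom[m[1]]   # co-located: distance 0 => r = 0
    map <- linkage_map(loci, chrom[loci], rep(0, length(loci)))
  }
  structure(list(scenario = scenario, n_individuals = n_individuals,
                 map = map, merges = if (scenario == 2) merges else list(),
                 effects = effects),
            class = "scenario_spec")
}

scenario_loci <- function() {
  c("qGY-psr-2D.1", "qGY-psr-3A.2", "qGY-psr-3B.2",
    "qPH-psr-2A.1", "qPH-psr-2D", "qPH-psr-3A", "qPH-psr-3B.1",
    "qPH-psr-4D", "qPH-psr-5A.1",
    "qEM-psr-1B.2", "qEM-psr-1D.1", "qEM-psr-3A", "qEM-psr-5A",
    "qEM-psr-6A.1")
}

#' Simulate an SDH population
#'
#' Draws `n_individuals` doubled-haploid lines from gametes of the
#' Avalon x Cadenza F1 over the scenario panel. Under scenario 2 the
#' merged locus pairs are completely linked, so recombinant allele
#' combinations inside a merged pair never occur.
#'
#' @param spec A `scenario_spec`.
#' @return List with `pop` (the homozygous `line_population`) and
#'   `class_freq` (data frame of homozygous genotype classes with counts
#'   and percent frequencies summing to 100 over observed classes).
#' @export
simulate_sdh_population <- function(spec) {
  f1 <- make_f1(inbred_line("A", spec$map), inbred_line("C", spec$map))
  pop <- make_dh(expand_plant(f1, spec$n_individuals))
  list(pop = pop, class_freq = genotype_class_frequencies(pop))
}

#' Genotype-class frequencies of a homozygous population
#'
#' @param pop A fully homozygous `line_population`.
#' @return Data frame with columns `class` (allele-origin string over the
#'   map's loci), `count` and `frequency` (percent of the population).
#' @export
genotype_class_frequencies <- function(pop) {
  if (!all(is_homozygous(pop))) stop("population must be fully homozygous")
  lab <- c("A", "C")
  cls <- do.call(paste0, lapply(seq_len(ncol(pop$hap1)),
                                function(j) lab[pop$hap1[, j] + 1L]))
  tab <- table(cls)
  data.frame(class = names(tab), count = as.integer(tab),
             frequency = 100 * as.integer(tab) / n_plants(pop),
             stringsAsFactors = FALSE)
}

#' Trait distributions conditional on yield category
#'
#' Partitions a population into `n_categories` equal-width yield bins
#' (over the observed yield range) and summarises the height and
#' ear-emergence values found in each bin.
#'
#' @param pop A `line_population`.
#' @param effects Effect table covering traits `GY`, `PH`, `EM`.
#' @param n_categories Number of yield bins (default 6).
#' @param environment Environment label for the genotypic values.
#' @return List with `assignment` (bin index per plant) and `summary`
#'   (data frame: category, yield range, plant count, PH and EM ranges).
#'   A constant-yield population collapses to a single category.
#' @export
classify_by_yield <- function(pop, effects, n_categories = 6,
                              environment = "MET") {
  gy <- genotypic_value(pop, effects, "GY", environment)
  ph <- genotypic_value(pop, effects, "PH", environment)
  em <- genotypic_value(pop, effects, "EM", environment)
  rng <- range(gy)
  if (diff(rng) == 0) {
    bin <- rep(1L, length(gy)); breaks <- rng
  } else {
    breaks <- seq(rng[1], rng[2], length.out = n_categories + 1)
    bin <- findInterval(gy, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  }
  cats <- sort(unique(bin))
  summ <- do.call(rbind, lapply(cats, function(b) {
    i <- bin == b
    data.frame(category = b,
               gy_min = min(gy[i]), gy_max = max(gy[i]), n = sum(i),
               ph_min = min(ph[i]), ph_max = max(ph[i]),
               em_min = min(em[i]), em_max = max(em[i]))
  }))
  list(assignment = bin, breaks = breaks, summary = summ)
}

#' The nine reconstructed ideal SDH genotypes
#'
#' Returns nine ideal genotype patterns over the 14-locus scenario panel.
#' These are synthetic reconstructions consistent with the published
#' constraints — every pattern carries all favourable yield alleles and a
#' height/ear-emergence profile near the Avalon parent — not the study's
#' own (unpublished) line list. Three of the nine combine the 3A height
#' and ear-emergence alleles from different parents and are therefore
#' unattainable when that pair is pleiotropic.
#'
#' @return Character matrix (14 loci x 9 patterns) of allele origins.
#' @export
ideal_sdh_genotypes <- function() {
  path <- system.file("extdata", "ideal_sdh_synthetic.tsv",
                      package = "breedsimr", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab$locus_id
  m
}

#' Which ideal genotypes are attainable under a scenario?
#'
#' An ideal genotype is attainable under scenario 2 only if its alleles at
#' every merged (pleiotropic) locus pair derive from the same parent;
#' under scenario 1 every pattern is attainable.
#'
#' @param ideals Character matrix of allele origins (loci x patterns), as
#'   from [ideal_sdh_genotypes()].
#' @param spec A `scenario_spec`.
#' @return Logical vector over the patterns.
#' @export
attainable_ideal_genotypes <- function(ideals, spec) {
  if (length(ideals) == 0) return(logical(0))
  ok <- rep(TRUE, ncol(ideals))
  for (m in spec$merges) {
    if (!all(m %in% rownames(ideals)))
      stop("ideal patterns must specify alleles at merged loci: ",
           paste(m, collapse = ", "))
    ok <- ok & (ideals[m[1], ] == ideals[m[2], ])
  }
  stats::setNames(ok, colnames(ideals))
}
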