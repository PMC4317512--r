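#' Sample one gamete per plant
#'
#' Simulates meiosis for every plant of a population. Per chromosome the
#' gamete starts from a fair choice between the two parental haplotypes at
#' the first locus and switches haplotype between adjacent loci with the
#' recombination fraction given by the Haldane map function (no
#' interference). Loci on different chromosomes segregate independently.
#'
#' Uses the R random number generator; seed with [set.seed()] (or the
#' replicate-stream helpers) for reproducibility.
#'
#' @param pop A `line_population`.
#' @return Integer matrix (`n` x loci) of sampled gamete haplotypes (0 = A,
#'   1 = C).
#' @export
sample_gametes <- function(pop) {
  n <- n_plants(pop)
  L <- ncol(pop$hap1)
  if (n == 0 || L == 0) return(pop$hap1[0, , drop = FALSE])
  r <- map_link_r(pop$map)
  # state[, j]: TRUE = copy from hap2 at locus j
  state <- matrix(FALSE, n, L)
  u <- matrix(stats::runif(n * L), n, L)
  state[, 1] <- u[, 1] < 0.5
  if (L > 1) for (j in 2:L) state[, j] <- xor(state[, j - 1], u[, j] < r[j])
  g <- pop$hap1
  g[state] <- pop$hap2[state]
  g
}

#' Cross two homozygous lines
#'
#' Produces the F1 of two fully homozygous (inbred or doubled-haploid)
#' parents: one haplotype from each parent, heterozygous exactly where the
#' parents differ.
#'
#' @param p1,p2 Single-plant homozygous `line_population` objects on the
#'   same map.
#' @return A single-plant `line_population` (the F1).
#' @export
make_f1 <- function(p1, p2) {
  if (n_plants(p1) != 1 || n_plants(p2) != 1) stop("parents must be single plants")
  if (!identical(p1$map$locus, p2$map$locus)) stop("parents must share a map")
  if (!all(is_homozygous(p1)) || !all(is_homozygous(p2)))
    stop("parents must be fully homozygous")
  line_population(p1$hap1, p2$hap1, p1$map)
}

#' Replicate a single plant into a population
#' @param plant Single-plant `line_population`.
#' @param n Number of copies.
#' @return A `line_population` of `n` identical plants.
#' @export
expand_plant <- function(plant, n) {
  if (n_plants(plant) != 1) stop("expected a single plant")
  line_population(plant$hap1[rep(1L, n), , drop = FALSE],
                  plant$hap2[rep(1L, n), , drop = FALSE], plant$map)
}

#' Self plants
#'
#' Each offspring is formed from two independent gametes of its (single)
#' parent plant.
#'
#' @param pop A `line_population` of candidate parents.
#' @param parent Integer vector of parent indices, one per offspring
#'   (defaults to one self-seed per plant).
#' @return A `line_population` of offspring.
#' @export
self_plants <- function(pop, parent = seq_len(n_plants(pop))) {
  sub <- subset_plants(pop, parent)
  line_population(sample_gametes(sub), sample_gametes(sub), pop$map)
}

#' Derive doubled-haploid lines
#'
#' One gamete is sampled per (possibly repeated) donor plant and doubled
#' into a fully homozygous line.
#'
#' @param pop A `line_population` of donor plants.
#' @param parent Integer vector of donor indices, one per DH line
#'   (defaults to one DH per plant).
#' @return A fully homozygous `line_population`.
#' @export
make_dh <- function(pop, parent = seq_len(n_plants(pop))) {
  g <- sample_gametes(subset_plants(pop, parent))
  line_population(g, g, pop$map)
}

#' Generate an F2 population
#'
#' Selfs an F1 plant `n` times (two independent gametes per seed).
#'
#' @param f1 Single-plant `line_population`.
#' @param n F2 population size.
#' @return A `line_population` of `n` F2 plants.
#' @export
make_f2 <- function(f1, n) {
  self_plants(expand_plant(f1, n))
}
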