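#' The packaged Avalon x Cadenza fixture
#'
#' Loads the packaged 23-locus selection panel: the linkage map, the five
#' DH parents (DH27, DH61, DH182, DH109, DH160) together with the Avalon
#' and Cadenza allele patterns, the target genotype, and the additive
#' effect table. Genotypes reproduce the published parental panel
#' cell-for-cell; chromosome assignments are parsed from locus names.
#' Map positions within a chromosome are package defaults (the study's
#' own marker positions are not reproduced here) and can be overridden by
#' supplying a different locus table.
#'
#' Effect rows carry a `provenance` flag: `paper` for printed magnitudes
#' and directions, `synthetic` for stand-in values chosen at the printed
#' orders of magnitude.
#'
#' @param map_path,genotype_path,effects_path Optional paths overriding
#'   the packaged TSVs.
#' @return List with elements `map` (a `linkage_map`), `parents` (named
#'   list of single-plant homozygous `line_population`s, including
#'   `Avalon` and `Cadenza` patterns), `target` (a `target_genotype`) and
#'   `effects` (data frame).
#' @export
avalon_cadenza_fixture <- function(map_path = NULL, genotype_path = NULL,
                                   effects_path = NULL) {
  p <- function(x) system.file("extdata", x, package = "breedsimr", mustWork = TRUE)
  if (is.null(map_path)) map_path <- p("avalon_cadenza_map.tsv")
  if (is.null(genotype_path)) genotype_path <- p("avalon_cadenza_genotypes.tsv")
  if (is.null(effects_path)) effects_path <- p("avalon_cadenza_effects.tsv")
  map <- read_locus_table(map_path)$map
  gt <- utils::read.delim(genotype_path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("locus_id", "DH27", "DH61", "DH182", "DH109", "DH160", "target")
  if (nrow(gt) != 23 || !all(need %in% names(gt)) ||
      !all(unlist(gt[setdiff(need, "locus_id")]) %in% c("AA", "CC")))
    stop("packaged genotype table failed its integrity check")
  pops <- read_genotype_table(genotype_path, map)
  target_codes <- gt$target[match(map$locus, gt$locus_id)]
  parents <- pops[setdiff(names(pops), "target")]
  parents$Avalon <- inbred_line("A", map)
  parents$Cadenza <- inbred_line("C", map)
  effects <- utils::read.delim(effects_path, stringsAsFactors = FALSE)
  list(map = map,
       parents = parents,
       target = target_genotype(map$locus,
                                ifelse(target_codes == "AA", "A", "C")),
       effects = effects)
}

#' Generate a synthetic biparental cross
#'
#' Builds a synthetic stand-in fixture with the same structure as the
#' packaged panel: two fully homozygous parents differing at `k_loci`
#' biallelic loci, a target genotype mixing both parents' alleles, and
#' additive effects at field-realistic magnitudes (yield ~0.1-0.4 t/ha,
#' height ~1-5 cm, ear emergence on a percent scale). Uses the R random
#' number generator (seed with [set.seed()]).
#'
#' @param k_loci Number of segregating loci (>= 1).
#' @param n_chromosomes Number of chromosomes to spread loci over
#'   (ignored for `linkage_profile = "independent"`).
#' @param linkage_profile `"independent"` (every locus on its own
#'   chromosome) or `"clustered"` (a linked cluster plus independent
#'   loci, mimicking a multi-locus chromosome group).
#' @param effect_scale Multiplier anchoring the largest yield effect at
#'   `0.37 * effect_scale` t/ha.
#' @param cluster_size,cluster_span For `"clustered"`: number of loci in
#'   the linked cluster (must not exceed `k_loci`) and the cM span they
#'   occupy.
#' @return List with `map`, `parents` (list `p1`, `p2`), `target`,
#'   `effects` (provenance flagged `synthetic`).
#' @export
generate_synthetic_cross <- function(k_loci, n_chromosomes = k_loci,
                                     linkage_profile = c("independent", "clustered"),
                                     effect_scale = 1,
                                     cluster_size = min(5, k_loci),
                                     cluster_span = 40) {
  linkage_profile <- match.arg(linkage_profile)
  if (k_loci < 1) stop("k_loci must be at least 1")
  ids <- sprintf("syn_%02d", seq_len(k_loci))
  if (linkage_profile == "independent") {
    chrom <- paste0("chr_", seq_len(k_loci))
    pos <- rep(0, k_loci)
  } else {
    if (cluster_size > k_loci) stop("cluster_size exceeds k_loci")
    chrom <- c(rep("chr_1", cluster_size),
               paste0("chr_", 1 + seq_len(k_loci - cluster_size)))
    pos <- c(seq(0, cluster_span, length.out = max(cluster_size, 2))[seq_len(cluster_size)],
             rep(0, k_loci - cluster_size))
  }
  map <- linkage_map(ids, chrom, pos)
  p1 <- inbred_line("A", map)
  p2 <- inbred_line("C", map)
  origin <- sample(c("A", "C"), k_loci, replace = TRUE)
  if (k_loci >= 2 && length(unique(origin)) == 1)   # target mixes both parents
    origin[sample.int(k_loci, 1)] <- setdiff(c("A", "C"), origin[1])
  target <- target_genotype(map$locus, origin[match(map$locus, ids)])
  trait <- rep(c("GY", "PH", "EM"), length.out = k_loci)
  eff <- numeric(k_loci)
  eff[trait == "GY"] <- stats::runif(sum(trait == "GY"), 0.1, 0.4)
  if (any(trait == "GY"))
    eff[trait == "GY"] <- eff[trait == "GY"] *
      (0.37 * effect_scale / max(eff[trait == "GY"]))
  eff[trait == "PH"] <- stats::runif(sum(trait == "PH"), 1, 5) * effect_scale
  eff[trait == "EM"] <- stats::runif(sum(trait == "EM"), 0.5, 3) * effect_scale
  effects <- data.frame(locus_id = ids, trait = trait, environment = "MET",
                        additive_effect = round(eff, 3),
                        increasing_parent = sample(c("A", "C"), k_loci, replace = TRUE),
                        provenance = "synthetic", stringsAsFactors = FALSE)
  list(map = map, parents = list(p1 = p1, p2 = p2), target = target,
       effects = effects)
}

#' Write fixture TSVs
#'
#' Serialises a fixture (as returned by [avalon_cadenza_fixture()] or
#' [generate_synthetic_cross()]) to the package's TSV interchange formats:
#' a locus table (map + effects) and a genotype table (parents + target).
#'
#' @param fixture Fixture list with `map`, `parents`, `target`, `effects`.
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix.
#' @return Invisibly, the paths written.
#' @export
write_fixture <- function(fixture, dir, prefix = "fixture") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  locus_path <- file.path(dir, paste0(prefix, "_loci.tsv"))
  geno_path <- file.path(dir, paste0(prefix, "_genotypes.tsv"))
  write_locus_table(fixture$map, fixture$effects, locus_path)
  pops <- fixture$parents
  pops$target <- inbred_line(unclass(fixture$target)[fixture$map$locus],
                             fixture$map)
  write_genotype_table(pops, geno_path)
  invisible(c(loci = locus_path, genotypes = geno_path))
}

#' Read fixture TSVs written by [write_fixture()]
#'
#' @param dir Directory holding the TSVs.
#' @param prefix File name prefix used when writing.
#' @return Fixture list with `map`, `parents`, `target`, `effects`.
#' @export
read_fixture <- function(dir, prefix = "fixture") {
  lt <- read_locus_table(file.path(dir, paste0(prefix, "_loci.tsv")))
  pops <- read_genotype_table(file.path(dir, paste0(prefix, "_genotypes.tsv")),
                              lt$map)
  target_pop <- pops$target
  tc <- genotype_codes(target_pop)[1, ]
  list(map = lt$map, parents = pops[setdiff(names(pops), "target")],
       target = target_genotype(lt$map$locus, ifelse(tc == "AA", "A", "C")),
       effects = lt$effects)
}
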