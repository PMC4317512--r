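#' Haldane map function
#'
#' Converts a map distance in centimorgans to a recombination fraction
#' assuming no crossover interference: r = (1 - exp(-2d/100)) / 2.
#'
#' @param d Numeric vector of map distances in cM; must be non-negative.
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @examples
#' recombination_fraction(0)    # 0
#' recombination_fraction(10)   # ~0.0906
#' @export
recombination_fraction <- function(d) {
  if (!is.numeric(d) || anyNA(d)) stop("map distance must be numeric and non-missing")
  if (any(d < 0)) stop("map distance must be non-negative")
  0.5 * (1 - exp(-2 * d / 100))
}

#' Build a linkage map
#'
#' A linkage map is an ordered table of biallelic loci grouped by
#' chromosome and sorted by position (cM from the first locus on the
#' chromosome). Positions are chromosome-local; only distances between
#' adjacent loci matter for recombination.
#'
#' @param locus Character vector of unique locus identifiers.
#' @param chrom Character vector of chromosome labels.
#' @param pos Numeric vector of map positions in cM (>= 0).
#' @return A data frame of class `linkage_map` with columns
#'   `locus`, `chrom`, `pos`, ordered by chromosome then position.
#' @export
linkage_map <- function(locus, chrom, pos) {
  if (anyDuplicated(locus)) stop("locus ids must be unique")
  if (length(locus) != length(chrom) || length(locus) != length(pos))
    stop("locus, chrom and pos must have equal length")
  if (any(pos < 0)) stop("map positions must be non-negative")
  chrom <- as.character(chrom)
  # keep chromosomes in order of first appearance, loci by position within
  ord <- order(match(chrom, unique(chrom)), pos)
  map <- data.frame(locus = as.character(locus)[ord], chrom = chrom[ord],
                    pos = as.numeric(pos)[ord], stringsAsFactors = FALSE)
  class(map) <- c("linkage_map", "data.frame")
  map
}

#' @export
print.linkage_map <- function(x, ...) {
  cat("Linkage map:", nrow(x), "loci on", length(unique(x$chrom)),
      "chromosome(s)\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Adjacent-locus recombination fractions of a map
#'
#' For each locus, the recombination fraction with the previous locus in
#' map order; 0.5 at the first locus of each chromosome (free
#' recombination across chromosomes, and a fair starting haplotype draw).
#'
#' @param map A `linkage_map`.
#' @return Numeric vector of length `nrow(map)`.
#' @keywords internal
map_link_r <- function(map) {
  n <- nrow(map)
  r <- rep(0.5, n)
  if (n > 1) {
    same <- map$chrom[-1] == map$chrom[-n]
    d <- map$pos[-1] - map$pos[-n]
    r[-1][same] <- recombination_fraction(d[same])
  }
  r
}

#' Rearrange a map so every locus is on its own chromosome
#'
#' Forces independent segregation of all loci (recombination fraction 0.5
#' between every pair) while keeping locus identities. Used for
#' closed-form oracle comparisons.
#'
#' @param map A `linkage_map`.
#' @return A `linkage_map` with one locus per pseudo-chromosome.
#' @export
unlink_map <- function(map) {
  linkage_map(map$locus, paste0("chr_", seq_len(nrow(map))), rep(0, nrow(map)))
}

#' Read a locus table
#'
#' Reads a tab-separated locus table with columns `locus_id`, `chromosome`,
#' `pos_cM`, and optionally the per-trait effect columns `trait`,
#' `environment`, `additive_effect`, `increasing_parent` (one row per
#' locus x trait x environment). Returns the linkage map and the effect
#' table.
#'
#' @param path Path to a TSV file.
#' @return List with elements `map` (a `linkage_map`) and `effects`
#'   (data frame, possibly empty).
#' @export
read_locus_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("locus_id", "chromosome", "pos_cM")
  if (!all(need %in% names(tab))) stop("locus table needs columns: ",
                                       paste(need, collapse = ", "))
  u <- !duplicated(tab$locus_id)
  map <- linkage_map(tab$locus_id[u], tab$chromosome[u], tab$pos_cM[u])
  eff_cols <- c("trait", "environment", "additive_effect", "increasing_parent")
  effects <- if (all(eff_cols %in% names(tab))) {
    e <- tab[!is.na(tab$trait) & tab$trait != "", c("locus_id", eff_cols,
         intersect("provenance", names(tab)))]
    rownames(e) <- NULL
    e
  } else data.frame()
  list(map = map, effects = effects)
}

#' Write a locus table
#'
#' Inverse of [read_locus_table()]: writes map and effect rows to one TSV.
#'
#' @param map A `linkage_map`.
#' @param effects Effect table (may be `NULL` or empty).
#' @param path Output path.
#' @export
write_locus_table <- function(map, effects = NULL, path) {
  base <- data.frame(locus_id = map$locus, chromosome = map$chrom,
                     pos_cM = map$pos, stringsAsFactors = FALSE)
  if (!is.null(effects) && nrow(effects)) {
    out <- merge(base, effects, by = "locus_id", all.x = TRUE, sort = FALSE)
    out <- out[order(match(out$locus_id, map$locus)), ]
  } else out <- base
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
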