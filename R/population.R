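#' Populations of phased line genotypes
#'
#' A population stores, for `n` plants, two haplotypes aligned to a
#' linkage map. Alleles are coded by parental origin: `"A"` (Avalon-derived,
#' the "QQ" state) and `"C"` (Cadenza-derived, "qq"). Internally each
#' haplotype is an integer matrix (`n` x loci) with 0 = A and 1 = C.
#'
#' @param hap1,hap2 Integer matrices (`n` x loci) with values 0/1.
#' @param map The `linkage_map` the columns are aligned to.
#' @return An object of class `line_population`.
#' @export
line_population <- function(hap1, hap2, map) {
  hap1 <- as.matrix(hap1); hap2 <- as.matrix(hap2)
  storage.mode(hap1) <- "integer"; storage.mode(hap2) <- "integer"
  if (!identical(dim(hap1), dim(hap2))) stop("haplotype matrices must have equal dimensions")
  if (ncol(hap1) != nrow(map)) stop("haplotype length must equal locus count of the map")
  if (length(hap1) && !all(hap1 %in% c(0L, 1L) & hap2 %in% c(0L, 1L)))
    stop("alleles must be coded 0 (A) or 1 (C)")
  colnames(hap1) <- colnames(hap2) <- map$locus
  structure(list(hap1 = hap1, hap2 = hap2, map = map),
            class = "line_population")
}

#' @export
print.line_population <- function(x, ...) {
  cat("line_population:", nrow(x$hap1), "plant(s),", ncol(x$hap1), "loci\n")
  invisible(x)
}

#' Number of plants in a population
#' @param pop A `line_population`.
#' @return Integer count.
#' @export
n_plants <- function(pop) nrow(pop$hap1)

#' Subset a population by plant index
#' @param pop A `line_population`.
#' @param i Integer (or logical) index of plants.
#' @return A `line_population` with the selected plants.
#' @export
subset_plants <- function(pop, i) {
  line_population(pop$hap1[i, , drop = FALSE], pop$hap2[i, , drop = FALSE], pop$map)
}

#' Is every plant fully homozygous?
#' @param pop A `line_population`.
#' @return Logical vector, one entry per plant.
#' @export
is_homozygous <- function(pop) {
  if (ncol(pop$hap1) == 0) return(rep(TRUE, n_plants(pop)))
  rowSums(pop$hap1 != pop$hap2) == 0L
}

#' Per-plant heterozygosity
#' @param pop A `line_population`.
#' @return Fraction of heterozygous loci per plant.
#' @export
heterozygosity <- function(pop) rowMeans(pop$hap1 != pop$hap2)

#' Convert a population to genotype codes
#'
#' @param pop A `line_population`.
#' @return Character matrix (`n` x loci) with entries `"AA"`, `"CC"` or `"AC"`
#'   (heterozygotes are reported `"AC"` regardless of phase).
#' @export
genotype_codes <- function(pop) {
  g <- pop$hap1 + pop$hap2
  out <- matrix(c("AA", "AC", "CC")[g + 1L], nrow(g), ncol(g),
                dimnames = dimnames(pop$hap1))
  out
}

#' Build a population from genotype codes
#'
#' @param codes Character matrix (`n` x loci, columns named by locus) with
#'   entries in `AA`, `CC`, `AC`; column order may differ from the map and
#'   is realigned by locus id.
#' @param map A `linkage_map`.
#' @return A `line_population`. Heterozygous `AC` entries are phased
#'   arbitrarily as A on haplotype 1.
#' @export
population_from_codes <- function(codes, map) {
  codes <- as.matrix(codes)
  if (is.null(colnames(codes))) stop("genotype code matrix must have locus column names")
  miss <- setdiff(map$locus, colnames(codes))
  if (length(miss)) stop("genotype table is missing loci: ", paste(miss, collapse = ", "))
  codes <- codes[, map$locus, drop = FALSE]
  ok <- codes %in% c("AA", "CC", "AC", "CA")
  if (!all(ok)) stop("genotype codes must be AA, CC or AC")
  h1 <- (codes == "CC" | codes == "CA") * 1L
  h2 <- (codes == "CC" | codes == "AC") * 1L
  dim(h1) <- dim(h2) <- dim(codes)
  line_population(h1, h2, map)
}

#' Read a genotype table
#'
#' Reads a TSV with a `locus_id` column and one column per line; values in
#' `AA`, `CC`, `AC`.
#'
#' @param path Path to a TSV file.
#' @param map A `linkage_map` used to order and validate loci.
#' @return A named list of single-plant `line_population` objects, one per
#'   line column.
#' @export
read_genotype_table <- function(path, map) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"locus_id" %in% names(tab)) stop("genotype table needs a locus_id column")
  lines <- setdiff(names(tab), "locus_id")
  out <- lapply(lines, function(nm) {
    codes <- matrix(tab[[nm]], nrow = 1, dimnames = list(NULL, tab$locus_id))
    population_from_codes(codes, map)
  })
  names(out) <- lines
  out
}

#' Write a genotype table
#'
#' @param pops Named list of `line_population` objects (each of any size;
#'   plants are written as `<name>` or `<name>_i`).
#' @param path Output path.
#' @export
write_genotype_table <- function(pops, path) {
  stopifnot(length(pops) > 0)
  map <- pops[[1]]$map
  cols <- list(locus_id = map$locus)
  for (nm in names(pops)) {
    g <- genotype_codes(pops[[nm]])
    for (i in seq_len(nrow(g))) {
      cn <- if (nrow(g) == 1) nm else paste0(nm, "_", i)
      cols[[cn]] <- g[i, ]
    }
  }
  utils::write.table(as.data.frame(cols, check.names = FALSE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Make a fully homozygous line from a haplotype pattern
#'
#' @param origin Character vector over the map's loci with entries `"A"`/`"C"`,
#'   or a single value recycled to all loci.
#' @param map A `linkage_map`.
#' @return A single-plant homozygous `line_population`.
#' @export
inbred_line <- function(origin, map) {
  origin <- rep_len(origin, nrow(map))
  if (!all(origin %in% c("A", "C"))) stop("allele origins must be 'A' or 'C'")
  h <- matrix(as.integer(origin == "C"), 1, nrow(map))
  line_population(h, h, map)
}

#' Bind populations by row
#' @param ... `line_population` objects on the same map.
#' @return Combined `line_population`.
#' @export
bind_populations <- function(...) {
  pops <- list(...)
  map <- pops[[1]]$map
  if (!all(vapply(pops, function(p) identical(p$map$locus, map$locus), logical(1))))
    stop("populations must share a map")
  line_population(do.call(rbind, lapply(pops, `[[`, "hap1")),
                  do.call(rbind, lapply(pops, `[[`, "hap2")), map)
}
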