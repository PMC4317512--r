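# Independent exact-enumeration oracle for F2-enrichment strategies.
#
# Computes, per chromosome, the exact probability that an F2 plant survives
# enrichment, and the exact conditional probabilities that a DH line (or an
# F6 plant after four rounds of selfing) derived from a surviving plant is
# the full target. Gamete distributions come from a forward pass over locus
# patterns (an HMM over the two parental haplotypes); selfing is an exact
# transition over haplotype-pair states. None of this shares code with the
# simulation path it checks.

oracle_gamete_dist <- function(h1, h2, r) {
  m <- length(h1)
  pats <- as.matrix(expand.grid(rep(list(0:1), m)))[, m:1, drop = FALSE]
  probs <- numeric(nrow(pats))
  for (i in seq_len(nrow(pats))) {
    x <- pats[i, ]
    a <- c(if (h1[1] == x[1]) 0.5 else 0, if (h2[1] == x[1]) 0.5 else 0)
    if (m > 1) for (j in 2:m) {
      t1 <- a[1] * (1 - r[j]) + a[2] * r[j]
      t2 <- a[1] * r[j] + a[2] * (1 - r[j])
      a <- c(if (h1[j] == x[j]) t1 else 0, if (h2[j] == x[j]) t2 else 0)
    }
    probs[i] <- sum(a)
  }
  list(patterns = pats, probs = probs)
}

oracle_chrom <- function(h1, h2, tpat, r, self_steps = 4) {
  gd <- oracle_gamete_dist(h1, h2, r)
  pats <- gd$patterns
  np <- nrow(pats)
  tidx <- which(apply(pats, 1, function(x) all(x == tpat)))
  surv <- matrix(FALSE, np, np)
  for (i in seq_len(np)) for (j in seq_len(np))
    surv[i, j] <- all(pats[i, ] == tpat | pats[j, ] == tpat)
  cache <- vector("list", np * np)
  gd_pair <- function(i, j) {
    key <- (i - 1) * np + j
    if (is.null(cache[[key]]))
      cache[[key]] <<- oracle_gamete_dist(pats[i, ], pats[j, ], r)$probs
    cache[[key]]
  }
  pdh <- matrix(0, np, np)
  for (i in seq_len(np)) for (j in seq_len(np))
    if (surv[i, j]) pdh[i, j] <- gd_pair(i, j)[tidx]
  f <- matrix(0, np, np); f[tidx, tidx] <- 1
  for (step in seq_len(self_steps)) {
    fn <- matrix(0, np, np)
    for (i in seq_len(np)) for (j in seq_len(np)) {
      if (i > j) { fn[i, j] <- fn[j, i]; next }
      g <- gd_pair(i, j)
      fn[i, j] <- as.numeric(t(g) %*% f %*% g)
    }
    f <- fn
  }
  pp <- outer(gd$probs, gd$probs)
  ps <- sum(pp[surv])
  list(p_survive = ps,
       dh_given_surv = sum((pp * pdh)[surv]) / ps,
       f6_given_surv = sum((pp * f)[surv]) / ps)
}

# Exact expectations for a cross on a map: P(F2 plant survives enrichment)
# and P(final line is the target | ancestor survived), multiplied over
# chromosomes (chromosomes segregate independently).
oracle_cross <- function(fixture, p1name, p2name, map = fixture$map) {
  p1 <- fixture$parents[[p1name]]
  p2 <- fixture$parents[[p2name]]
  seg <- segregating_loci(p1, p2, fixture$target)
  out <- c(p_survive = 1, p_dh = 1, p_f6 = 1)
  for (ch in unique(map$chrom)) {
    segl <- intersect(map$locus[map$chrom == ch], seg)
    if (!length(segl)) next
    pos <- map$pos[match(segl, map$locus)]
    r <- c(0.5, recombination_fraction(diff(pos)))
    ce <- oracle_chrom(p1$hap1[1, segl], p2$hap1[1, segl],
                       as.integer(unclass(fixture$target)[segl] == "C"), r)
    out <- out * c(ce$p_survive, ce$dh_given_surv, ce$f6_given_surv)
  }
  out
}

# Brute-force gamete frequencies for a single plant by direct simulation of
# many meioses (used to cross-check the vectorised meiosis engine).
mc_gamete_freq <- function(plant, n = 1e5) {
  g <- sample_gametes(expand_plant(plant, n))
  tab <- table(apply(g, 1, paste, collapse = ""))
  tab / n
}
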