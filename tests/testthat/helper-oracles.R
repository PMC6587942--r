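## Independent brute-force oracles used to cross-check the package's
## implementations. Deliberately written as direct transcriptions of the
## definitions (loops, explicit enumeration), not as copies of the
## package's vectorised code paths.

## two-locus LD statistics from a 2x2 haplotype count table
oracle_ld_from_counts <- function(n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  pA <- (n11 + n10) / n
  pB <- (n11 + n01) / n
  D <- n11 / n - pA * pB
  if (D >= 0) {
    dmax <- min(pA * (1 - pB), (1 - pA) * pB)
  } else {
    dmax <- min(pA * pB, (1 - pA) * (1 - pB))
  }
  list(D = D,
       Dprime = if (dmax > 0) abs(D) / dmax else 0,
       r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)))
}

## grid likelihood distribution over |D'| by direct product-of-powers
## normalisation (no log-space shortcut)
oracle_dprime_bounds <- function(n11, n10, n01, n00, step = 0.001) {
  n <- n11 + n10 + n01 + n00
  pA <- (n11 + n10) / n
  pB <- (n11 + n01) / n
  if (pA == 0 || pA == 1 || pB == 0 || pB == 1) return(c(NA, NA))
  D <- n11 / n - pA * pB
  sgn <- if (D >= 0) 1 else -1
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  grid <- seq(0, 1, by = step)
  lik <- numeric(length(grid))
  for (i in seq_along(grid)) {
    Dv <- sgn * grid[i] * dmax
    p <- c(pA * pB + Dv, pA * (1 - pB) - Dv,
           (1 - pA) * pB - Dv, (1 - pA) * (1 - pB) + Dv)
    p[p < 0] <- 0
    lik[i] <- p[1]^n11 * p[2]^n10 * p[3]^n01 * p[4]^n00
  }
  w <- lik / sum(lik)
  cw <- cumsum(w)
  c(grid[min(which(cw >= 0.05))], grid[min(which(cw >= 0.95))])
}

## enumerate the 2x2 table directly from raw allele vectors
oracle_counts <- function(a, b) {
  n11 <- 0; n10 <- 0; n01 <- 0; n00 <- 0
  for (i in seq_along(a)) {
    if (a[i] < 0 || b[i] < 0) next
    if (a[i] == 1 && b[i] == 1) n11 <- n11 + 1
    else if (a[i] == 1 && b[i] == 0) n10 <- n10 + 1
    else if (a[i] == 0 && b[i] == 1) n01 <- n01 + 1
    else n00 <- n00 + 1
  }
  c(n11, n10, n01, n00)
}

## all-pairs mean Hamming distance per bp for a window's allele matrix
## (rows = sites, cols = samples), pairwise-complete per site
oracle_window_pi <- function(al, win_size) {
  ns <- ncol(al)
  total <- 0
  for (s in seq_len(nrow(al))) {
    diffs <- 0; pairs <- 0
    for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
      if (al[s, i] < 0 || al[s, j] < 0) next
      pairs <- pairs + 1
      if (al[s, i] != al[s, j]) diffs <- diffs + 1
    }
    if (pairs > 0) total <- total + diffs / pairs
  }
  total / win_size
}

## exhaustive pedigree classification over every breakpoint subset and
## starting parent
oracle_classify <- function(h, ped) {
  fam <- c(ped$parentA, ped$parentB, ped$focal, ped$progeny)
  if (any(is.na(h[fam]))) return("other")
  hf <- h[[ped$focal]]; ha <- h[[ped$parentA]]; hb <- h[[ped$parentB]]
  if (all(h[fam] == h[[fam[1]]])) return("family_shared")
  if (!all(h[ped$progeny] == hf)) return("other")
  if (hf == ha && hf != hb) return("parentA_inherited")
  if (hf == hb && hf != ha) return("parentB_inherited")
  if (hf != ha && hf != hb) {
    f <- strsplit(hf, "")[[1]]
    a <- strsplit(ha, "")[[1]]
    b <- strsplit(hb, "")[[1]]
    L <- length(f)
    if (L >= 2) {
      for (nb in 1:(L - 1)) {
        for (cmb in utils::combn(L - 1, nb, simplify = FALSE)) {
          cuts <- c(0, cmb, L)
          for (p0 in 1:2) {
            ok <- TRUE; p <- p0
            for (si in seq_len(length(cuts) - 1)) {
              seg <- (cuts[si] + 1):cuts[si + 1]
              par <- if (p == 1) a else b
              if (!all(f[seg] == par[seg])) { ok <- FALSE; break }
              p <- 3 - p
            }
            if (ok) return("recombined")
          }
        }
      }
    }
  }
  "other"
}

## build a genotype matrix from an allele matrix (sites x samples)
mk_geno <- function(al, pos = NULL, chrom = NULL, ids = NULL) {
  al <- as.matrix(al)
  S <- nrow(al)
  if (is.null(pos)) pos <- seq_len(S) * 100L
  if (is.null(chrom)) chrom <- rep("chr1", S)
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(ncol(al)))
  genotype_matrix(chrom, pos, rep("A", S), rep("T", S), al, ids)
}

## allele vectors realising a 2x2 haplotype count table
alleles_from_counts <- function(n11, n10, n01, n00) {
  list(a = c(rep(1L, n11), rep(1L, n10), rep(0L, n01), rep(0L, n00)),
       b = c(rep(1L, n11), rep(0L, n10), rep(1L, n01), rep(0L, n00)))
}

## one block object with given haplotype strings
mk_block <- function(haps, block_id = "B00001") {
  k <- max(nchar(haps), na.rm = TRUE)
  list(block_id = block_id, chrom = "chr1", start = 100L,
       end = 100L + 100L * (k - 1L), snp_indices = seq_len(k),
       length = 100L * (k - 1L) + 1L, haplotypes = haps)
}
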