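## Pairwise linkage disequilibrium with likelihood-based confidence bounds
## on |D'|, and Gabriel-style haplotype-block partitioning.
##
## Because the panel is haploid-coded, two-locus haplotype counts are
## directly countable (no EM phasing): n11, n10, n01, n00 over
## pairwise-complete samples, where "1" is the alternate allele.

ld_grid_step <- 0.001

## 2x2 haplotype counts over pairwise-complete samples
haplotype_counts <- function(a, b) {
  ok <- a >= 0L & b >= 0L
  a <- a[ok]; b <- b[ok]
  c(n11 = sum(a == 1L & b == 1L), n10 = sum(a == 1L & b == 0L),
    n01 = sum(a == 0L & b == 1L), n00 = sum(a == 0L & b == 0L))
}

## core: D, D', r2 from counts; NULL status when undefined
ld_core <- function(n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  if (n < 2) return(list(status = "insufficient"))
  pA <- (n11 + n10) / n
  pB <- (n11 + n01) / n
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(list(status = "monomorphic"))
  D <- n11 / n - pA * pB
  Dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  list(status = "ok", n = n, pA = pA, pB = pB, D = D,
       Dprime = if (Dmax > 0) abs(D) / Dmax else 0,
       r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)))
}

## posterior-style normalised likelihood of |D'| on a fixed grid
## (Haploview-style: margins fixed at observed allele frequencies,
## haplotype frequencies reconstructed from each grid value of |D'| with
## the observed sign of D; multinomial likelihood normalised to a
## distribution over the grid)
dprime_grid_dist <- function(n11, n10, n01, n00, step = ld_grid_step) {
  core <- ld_core(n11, n10, n01, n00)
  if (core$status != "ok") return(NULL)
  s <- if (core$D >= 0) 1 else -1
  Dmax <- if (core$D >= 0)
    min(core$pA * (1 - core$pB), (1 - core$pA) * core$pB) else
    min(core$pA * core$pB, (1 - core$pA) * (1 - core$pB))
  if (Dmax <= 0) return(NULL)
  d <- seq(0, 1, by = step)
  Dd <- s * d * Dmax
  p <- cbind(core$pA * core$pB + Dd,
             core$pA * (1 - core$pB) - Dd,
             (1 - core$pA) * core$pB - Dd,
             (1 - core$pA) * (1 - core$pB) + Dd)
  p[p < 0] <- 0
  nn <- c(n11, n10, n01, n00)
  ll <- numeric(length(d))
  for (j in 1:4) if (nn[j] > 0) ll <- ll + nn[j] * log(p[, j])
  w <- exp(ll - max(ll))
  list(d = d, w = w / sum(w))
}

#' One-sided confidence bounds on |D'| from haplotype counts
#'
#' Evaluates the multinomial likelihood of the four observed two-locus
#' haplotype counts over a grid of |D'| values (step 0.001, allele
#' frequencies fixed at their observed values), normalises it to a
#' distribution over the grid, and returns its 5th and 95th percentiles as
#' the lower (`CL`) and upper (`CU`) confidence bounds. These are the
#' bounds entering the Gabriel strong-LD test (`CU >= 0.98` and
#' `CL >= 0.7`).
#'
#' @param counts numeric vector `(n11, n10, n01, n00)` of haplotype counts
#'   (alternate allele = "1"), total >= 2.
#' @return named numeric `c(CL, CU)`; `c(NA, NA)` when a margin is
#'   monomorphic (undefined signal).
#' @export
dprime_bounds <- function(counts) {
  stopifnot(length(counts) == 4)
  if (sum(counts) < 2)
    hb_stop("need total haplotype count >= 2", "hb_insufficient")
  counts <- unname(counts)
  g <- dprime_grid_dist(counts[1], counts[2], counts[3], counts[4])
  if (is.null(g)) return(c(CL = NA_real_, CU = NA_real_))
  cw <- cumsum(g$w)
  c(CL = g$d[which(cw >= 0.05)[1]], CU = g$d[which(cw >= 0.95)[1]])
}

#' Pairwise linkage disequilibrium between two sites
#'
#' With haplotype frequencies `pAB`, `pA`, `pB` counted directly from the
#' haploid-coded alleles (pairwise-complete samples): `D = pAB - pA*pB`;
#' `D' = D / Dmax` where `Dmax = min(pA(1-pB), (1-pA)pB)` for `D > 0` and
#' `min(pA*pB, (1-pA)(1-pB))` otherwise; `r2 = D^2 / (pA(1-pA)pB(1-pB))`.
#' Confidence bounds on |D'| come from [dprime_bounds()].
#'
#' @param a,b integer allele vectors for the two sites (codes 0/1/-1),
#'   aligned on the same samples.
#' @return an object of class `ld_stats`: list with `status` (`"ok"`,
#'   `"monomorphic"` or `"insufficient"`), and for `"ok"` the fields `D`,
#'   `Dprime` (= |D'|), `r2`, `CL`, `CU`, `n`.
#' @export
pairwise_ld <- function(a, b) {
  stopifnot(length(a) == length(b))
  cnt <- unname(haplotype_counts(a, b))
  core <- ld_core(cnt[1], cnt[2], cnt[3], cnt[4])
  if (core$status != "ok")
    return(structure(list(status = core$status), class = "ld_stats"))
  bounds <- dprime_bounds(cnt)
  structure(list(status = "ok", D = core$D, Dprime = core$Dprime,
                 r2 = core$r2, CL = unname(bounds["CL"]),
                 CU = unname(bounds["CU"]), n = core$n),
            class = "ld_stats")
}

#' @export
print.ld_stats <- function(x, ...) {
  if (x$status != "ok") {
    cat(sprintf("ld_stats: undefined (%s)\n", x$status))
  } else {
    cat(sprintf("ld_stats: D=%.4f |D'|=%.4f r2=%.4f CI[%.3f, %.3f] n=%d\n",
                x$D, x$Dprime, x$r2, x$CL, x$CU, x$n))
  }
  invisible(x)
}

#' Partition chromosomes into haplotype blocks
#'
#' Sequential adjacent-pair scan per chromosome: the current block extends
#' from SNP i to SNP i+1 iff the pair is in strong LD under the Gabriel
#' bounds -- upper confidence bound on |D'| at least `cu_min` (consistent
#' with no historical recombination) and lower bound at least `cl_min` --
#' and the point estimate |D'| is at least `dprime_break`. When the pair
#' fails (including undefined LD at monomorphic sites), the block is
#' closed and the next one begins at SNP i+1. Single-SNP blocks are
#' discarded. Per-sample haplotype strings over the block's SNPs are
#' attached; a sample with any missing allele in the block gets an `NA`
#' string.
#'
#' This is the O(S) scan described by the block-definition rule itself,
#' not Haploview's exhaustive all-pairs search; on panels whose LD is
#' genuinely block-structured the two agree.
#'
#' @param m a [genotype_matrix] (coordinate-sorted).
#' @param cu_min minimum upper confidence bound on |D'| (default 0.98).
#' @param cl_min minimum lower confidence bound (default 0.7).
#' @param dprime_break additional point-estimate threshold below which a
#'   pair always breaks the block (default 0.7).
#' @return an object of class `haplotype_blocks`: a list of blocks, each a
#'   list with `block_id`, `chrom`, `start`, `end` (bp of first/last SNP),
#'   `snp_indices` (row indices into `m`), `length` (bp) and `haplotypes`
#'   (named character vector per sample). Empty matrix gives an empty
#'   list.
#' @export
partition_blocks <- function(m, cu_min = 0.98, cl_min = 0.7,
                             dprime_break = 0.7) {
  stopifnot(inherits(m, "genotype_matrix"))
  blocks <- list()
  for (ch in unique(m$chrom)) {
    idx <- which(m$chrom == ch)
    if (length(idx) < 2) next
    pass <- logical(length(idx) - 1)
    for (i in seq_len(length(idx) - 1)) {
      ld <- pairwise_ld(m$alleles[idx[i], ], m$alleles[idx[i + 1], ])
      pass[i] <- ld$status == "ok" && !is.na(ld$CU) &&
        ld$CU >= cu_min && ld$CL >= cl_min && ld$Dprime >= dprime_break
    }
    r <- rle(pass)
    at <- 1L
    for (j in seq_along(r$lengths)) {
      if (r$values[j]) {
        sites <- idx[at:(at + r$lengths[j])]
        blocks[[length(blocks) + 1]] <- list(
          chrom = ch, start = m$pos[sites[1]],
          end = m$pos[sites[length(sites)]], snp_indices = sites)
      }
      at <- at + r$lengths[j]
    }
  }
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    b$block_id <- sprintf("B%05d", i)
    b$length <- b$end - b$start + 1L
    b$haplotypes <- block_hap_strings(m, b$snp_indices)
    blocks[[i]] <- b
  }
  structure(blocks, class = "haplotype_blocks")
}

## per-sample allele strings over a site-index set; NA if any allele missing
block_hap_strings <- function(m, snp_indices) {
  al <- m$alleles[snp_indices, , drop = FALSE]
  out <- apply(al, 2, function(col)
    if (any(col < 0L)) NA_character_ else paste(col, collapse = ""))
  setNames(as.character(out), m$sample_ids)
}

#' Build block objects at given site-index intervals
#'
#' Constructs `haplotype_blocks` directly from known SNP index runs (e.g.
#' the truth table of [simulate_panel()]), bypassing LD detection. Used
#' to classify blocks at planted coordinates.
#'
#' @param m a [genotype_matrix].
#' @param intervals data.frame with columns `chrom`, `start`, `end` (bp,
#'   first/last SNP positions) and optionally `block_id`.
#' @return a `haplotype_blocks` list.
#' @export
blocks_from_intervals <- function(m, intervals) {
  blocks <- vector("list", nrow(intervals))
  for (i in seq_len(nrow(intervals))) {
    sites <- which(m$chrom == intervals$chrom[i] &
                   m$pos >= intervals$start[i] & m$pos <= intervals$end[i])
    blocks[[i]] <- list(
      chrom = intervals$chrom[i], start = intervals$start[i],
      end = intervals$end[i], snp_indices = sites,
      block_id = if ("block_id" %in% names(intervals))
        as.character(intervals$block_id[i]) else sprintf("B%05d", i),
      length = intervals$end[i] - intervals$start[i] + 1L,
      haplotypes = block_hap_strings(m, sites))
  }
  structure(blocks, class = "haplotype_blocks")
}

#' @export
print.haplotype_blocks <- function(x, ...) {
  cat(sprintf("haplotype_blocks: %d block(s)\n", length(x)))
  if (length(x) > 0) {
    df <- as.data.frame(x)
    cat(sprintf("  SNPs per block: %s; length (bp): median %d\n",
                paste(range(df$n_snps), collapse = "-"),
                as.integer(stats::median(df$length))))
  }
  invisible(x)
}

#' @export
as.data.frame.haplotype_blocks <- function(x, ...) {
  data.frame(block_id = vapply(x, `[[`, "", "block_id"),
             chrom = vapply(x, `[[`, "", "chrom"),
             start = vapply(x, function(b) as.integer(b$start), 0L),
             end = vapply(x, function(b) as.integer(b$end), 0L),
             n_snps = vapply(x, function(b) length(b$snp_indices), 0L),
             length = vapply(x, function(b) as.integer(b$length), 0L),
             stringsAsFactors = FALSE)
}

#' Write blocks as BED-like TSV plus a haplotype table
#'
#' The main table is 0-based half-open (`start-1`, `end`) in BED style;
#' the companion table holds per-sample allele strings.
#'
#' @param blocks a `haplotype_blocks` object.
#' @param path output TSV for block intervals.
#' @param hap_path optional output TSV for block x sample haplotype
#'   strings.
#' @return `path`, invisibly.
#' @export
write_blocks <- function(blocks, path, hap_path = NULL) {
  df <- as.data.frame(blocks)
  bed <- data.frame(chrom = df$chrom, start = df$start - 1L, end = df$end,
                    block_id = df$block_id, n_snps = df$n_snps)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(hap_path)) {
    hap <- do.call(rbind, lapply(blocks, function(b)
      data.frame(block_id = b$block_id, sample = names(b$haplotypes),
                 haplotype = ifelse(is.na(b$haplotypes), ".",
                                    b$haplotypes),
                 stringsAsFactors = FALSE)))
    utils::write.table(hap, hap_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
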