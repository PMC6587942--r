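## Sliding-window nucleotide diversity, Fst and log diversity-ratio scan
## between a tolerant and a sensitive trait group, and top-tail selection
## of candidate sweep regions.

## per-site mean pairwise difference within a sample set (haploid-coded,
## pairwise-complete): 2*n0*n1 / (n*(n-1)); 0 when fewer than 2 calls
site_pi_within <- function(al) {
  n1 <- rowSums(al == 1L)
  n0 <- rowSums(al == 0L)
  n <- n0 + n1
  ifelse(n >= 2, 2 * n0 * n1 / (n * (n - 1)), 0)
}

## per-site mean pairwise difference across two sample sets
site_pi_between <- function(alR, alS) {
  n1R <- rowSums(alR == 1L); n0R <- rowSums(alR == 0L)
  n1S <- rowSums(alS == 1L); n0S <- rowSums(alS == 0L)
  nR <- n1R + n0R; nS <- n1S + n0S
  ifelse(nR >= 1 & nS >= 1, (n0R * n1S + n1R * n0S) / (nR * nS), 0)
}

#' Per-bp nucleotide diversity in one window
#'
#' Sums, over the window's SNPs, the mean pairwise allele difference among
#' the given samples' haplotypes (pairwise-complete observations), and
#' divides by the window span in bp.
#'
#' @param m a [genotype_matrix].
#' @param samples sample ids to use (>= 2).
#' @param chrom chromosome of the window.
#' @param win_start 1-based window start (bp).
#' @param win_size window span in bp; the window is
#'   `[win_start, win_start + win_size - 1]`.
#' @return per-bp diversity (theta-pi). Windows where no site has two
#'   informative haplotypes give 0 with attribute `zero_information = TRUE`.
#' @export
window_pi <- function(m, samples, chrom, win_start, win_size) {
  if (length(samples) < 2)
    hb_stop("need >= 2 samples for diversity", "hb_insufficient")
  idx <- which(m$chrom == chrom & m$pos >= win_start &
               m$pos <= win_start + win_size - 1)
  al <- m$alleles[idx, samples, drop = FALSE]
  contrib <- site_pi_within(al)
  out <- sum(contrib) / win_size
  n_inf <- sum(rowSums(al >= 0L) >= 2)
  if (n_inf == 0) attr(out, "zero_information") <- TRUE
  out
}

#' Fst from between- and within-group diversity
#'
#' `Fst = (piBetween - piWithin) / piBetween`, where the diversities are
#' average numbers of pairwise differences between two individuals sampled
#' from different groups (between) or from the same group (within).
#'
#' @param pi_between,pi_within per-bp diversities (vectors allowed).
#' @return Fst; `NA` (undefined flag) where `pi_between` is 0.
#' @export
fst <- function(pi_between, pi_within) {
  ifelse(pi_between > 0, (pi_between - pi_within) / pi_between, NA_real_)
}

#' Log diversity ratio between tolerant and sensitive groups
#'
#' @param pi_r tolerant-group diversity.
#' @param pi_s sensitive-group diversity.
#' @return `ln(pi_r / pi_s)` where both are positive, else `NA` (undefined
#'   flag).
#' @export
ln_ratio <- function(pi_r, pi_s) {
  ifelse(pi_r > 0 & pi_s > 0, log(pi_r / pi_s), NA_real_)
}

#' Sliding-window diversity and differentiation scan
#'
#' Tiles each chromosome with windows of `win_size` bp at `step` bp
#' (default 100 kb / 10 kb), and computes per window: SNP count, per-bp
#' diversity in the tolerant (`pi_r`) and sensitive (`pi_s`) groups,
#' between-group diversity, `fst()` with
#' `pi_within = (pi_r + pi_s) / 2`, and `ln_ratio()`. Windows truncated at
#' the chromosome end are kept and normalised by their actual span.
#'
#' @param m a [genotype_matrix].
#' @param groups a [group_spec]; both groups must be present in `m`.
#' @param win_size window size in bp (default 1e5).
#' @param step step size in bp (default 1e4).
#' @param chrom_len optional named vector of chromosome lengths; defaults
#'   to the last SNP position per chromosome.
#' @return data.frame of class `window_stats`: `chrom`, `win_start`,
#'   `win_end`, `n_snps`, `pi_r`, `pi_s`, `pi_between`, `fst`, `ln_ratio`.
#' @export
sweep_scan <- function(m, groups, win_size = 1e5, step = 1e4,
                       chrom_len = NULL) {
  stopifnot(inherits(groups, "group_spec"))
  if (n_sites(m) == 0) hb_stop("empty genotype matrix", "hb_empty_matrix")
  missing_ids <- setdiff(c(groups$tolerant, groups$sensitive),
                         m$sample_ids)
  if (length(missing_ids) > 0)
    hb_stop(sprintf("group samples absent from matrix: %s",
                    paste(missing_ids, collapse = ", ")), "hb_invalid")
  out <- list()
  for (ch in unique(m$chrom)) {
    idx <- which(m$chrom == ch)
    pos <- m$pos[idx]
    len <- if (!is.null(chrom_len) && ch %in% names(chrom_len))
      chrom_len[[ch]] else max(pos)
    starts <- window_starts(len, win_size, step)
    ends <- pmin(starts + win_size - 1, len)

    alR <- m$alleles[idx, groups$tolerant, drop = FALSE]
    alS <- m$alleles[idx, groups$sensitive, drop = FALSE]
    cR <- cumsum(site_pi_within(alR))
    cS <- cumsum(site_pi_within(alS))
    cB <- cumsum(site_pi_between(alR, alS))
    ## window sums via cumulative sums over the sorted site positions
    lo <- findInterval(starts - 1, pos)  # sites strictly before window
    hi <- findInterval(ends, pos)        # sites up to window end
    span <- ends - starts + 1
    sum_rng <- function(cs) ifelse(hi > lo,
                                   cs[pmax(hi, 1)] -
                                     ifelse(lo > 0, cs[pmax(lo, 1)], 0), 0)
    pi_r <- sum_rng(cR) / span
    pi_s <- sum_rng(cS) / span
    pi_b <- sum_rng(cB) / span
    out[[ch]] <- data.frame(chrom = ch, win_start = starts,
                            win_end = ends, n_snps = hi - lo,
                            pi_r = pi_r, pi_s = pi_s, pi_between = pi_b,
                            fst = fst(pi_b, (pi_r + pi_s) / 2),
                            ln_ratio = ln_ratio(pi_r, pi_s),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("window_stats", "data.frame")
  res
}

#' Select candidate sweep regions from window statistics
#'
#' Selects windows simultaneously in the top `tail` fraction by Fst and in
#' the chosen `tail` of the log diversity ratio (default: bottom tail,
#' i.e. diversity reduced in the tolerant group). The cutoff is the k-th
#' most extreme defined value with `k = ceiling(tail * n_defined)`; ties
#' at the cutoff are all included. Overlapping or book-ended selected
#' windows are merged into sweep regions.
#'
#' @param stats a `window_stats` data.frame from [sweep_scan()].
#' @param tail tail fraction (default 0.01, the top 1%).
#' @param ratio_direction `"bottom"` (default) selects the most negative
#'   log ratios; `"top"` the most positive.
#' @param ratio_absolute optional absolute threshold on the diversity
#'   ratio `pi_r/pi_s` used instead of the quantile tail (windows with
#'   ratio below it are eligible).
#' @return data.frame of class `sweep_regions`: `chrom`, `start`, `end`,
#'   `n_windows`, `window_ids` (semicolon-joined row indices of `stats`),
#'   `peak_fst`, `peak_ln_ratio`. Zero rows (with a warning) when no
#'   window has both statistics defined.
#' @export
select_candidates <- function(stats, tail = 0.01,
                              ratio_direction = c("bottom", "top"),
                              ratio_absolute = NULL) {
  ratio_direction <- match.arg(ratio_direction)
  defined <- !is.na(stats$fst) & !is.na(stats$ln_ratio)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_windows = integer(0),
                      window_ids = character(0), peak_fst = numeric(0),
                      peak_ln_ratio = numeric(0), stringsAsFactors = FALSE)
  class(empty) <- c("sweep_regions", "data.frame")
  if (!any(defined)) {
    warning("no window with defined fst and ln_ratio")
    return(empty)
  }
  k <- max(1L, ceiling(tail * sum(defined)))
  fst_cut <- sort(stats$fst[defined], decreasing = TRUE)[k]
  sel_fst <- defined & stats$fst >= fst_cut
  if (!is.null(ratio_absolute)) {
    sel_ratio <- defined & exp(stats$ln_ratio) <
      if (ratio_direction == "bottom") ratio_absolute else 1 / ratio_absolute
  } else if (ratio_direction == "bottom") {
    cut <- sort(stats$ln_ratio[defined])[k]
    sel_ratio <- defined & stats$ln_ratio <= cut
  } else {
    cut <- sort(stats$ln_ratio[defined], decreasing = TRUE)[k]
    sel_ratio <- defined & stats$ln_ratio >= cut
  }
  sel <- which(sel_fst & sel_ratio)
  if (length(sel) == 0) return(empty)
  regs <- list()
  for (ch in unique(stats$chrom[sel])) {
    si <- sel[stats$chrom[sel] == ch]
    ir <- IRanges::reduce(IRanges::IRanges(stats$win_start[si],
                                           stats$win_end[si]))
    ov <- IRanges::findOverlaps(IRanges::IRanges(stats$win_start[si],
                                                 stats$win_end[si]), ir)
    for (j in seq_along(ir)) {
      members <- si[S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == j]]
      regs[[length(regs) + 1]] <- data.frame(
        chrom = ch, start = IRanges::start(ir)[j], end = IRanges::end(ir)[j],
        n_windows = length(members),
        window_ids = paste(members, collapse = ";"),
        peak_fst = max(stats$fst[members]),
        peak_ln_ratio = stats$ln_ratio[members][
          which.max(abs(stats$ln_ratio[members]))],
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, regs)
  rownames(res) <- NULL
  class(res) <- c("sweep_regions", "data.frame")
  res
}

#' Write window statistics and sweep regions
#'
#' @param stats `window_stats` data.frame.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_window_stats <- function(stats, path) {
  utils::write.table(format(as.data.frame(stats), digits = 10,
                            scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_window_stats
#' @param regions `sweep_regions` data.frame; written as BED (0-based
#'   half-open).
#' @export
write_sweep_regions <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom, start = regions$start - 1L,
                    end = regions$end, name = sprintf("sweep%03d",
                                                      seq_len(nrow(regions))),
                    peak_fst = regions$peak_fst)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
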