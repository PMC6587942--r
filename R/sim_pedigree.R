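## Synthetic genotype panels with planted haplotype blocks, pedigree
## transmission and a differentiated sweep region, plus full ground truth.
##
## The generator emulates the statistical structure the downstream analysis
## assumes: a panel of ~20 haploid-coded inbred lines (two parents, one
## focal cultivar bred from them, five progeny bred from the focal line and
## unrelated co-parents, and a set of unrelated elite lines), with
## block-structured LD, Poisson crossovers per meiosis, and one genomic
## region where two trait groups differ in allele frequency and diversity.

#' Simulation configuration
#'
#' @param n_chrom number of chromosomes; named alternately `A01`, `D01`,
#'   `A02`, ... so both subgenomes are represented.
#' @param chrom_len chromosome length in bp.
#' @param n_blocks_per_chrom planted haplotype blocks per chromosome.
#' @param block_len_range min/max planted block length (bp, first to last
#'   SNP).
#' @param snps_per_block_range min/max SNPs per planted block.
#' @param crossover_rate expected crossovers per chromosome per meiosis
#'   (Poisson).
#' @param n_progeny progeny lines bred from the focal cultivar.
#' @param n_panel_extra unrelated elite panel lines (co-parents of the
#'   progeny and members of the trait groups). At least 4 to form groups.
#' @param sweep_region list `(chrom, start, end)` of the planted sweep, or
#'   `NULL` for none. Planted blocks never overlap the sweep region; the
#'   region carries its own independently segregating SNPs.
#' @param sweep_freq_delta allele-frequency difference between tolerant and
#'   sensitive groups at sweep sites, in `[0, 1]`. `0` disables the
#'   differentiation (null case).
#' @param sweep_pi_reduction fold-reduction of expected heterozygosity in
#'   the tolerant group inside the sweep region (default 5).
#' @param sweep_snp_spacing spacing of sweep-region SNPs in bp.
#' @param snp_background_spacing spacing of background SNPs (bp) planted
#'   in inter-block gaps, each segregating independently with allele
#'   frequency drawn Uniform(0.1, 0.9) across founder lines; they make
#'   every scan window informative, as in a dense resequencing panel.
#'   `Inf` disables them.
#' @param intra_block_crossovers if `FALSE` (default), crossover positions
#'   are snapped to inter-block gap midpoints so every planted block is
#'   transmitted intact; if `TRUE`, positions stay where they fall and may
#'   split planted blocks (used to exercise recombined-block
#'   classification).
#' @param seed integer RNG seed; equal seeds give byte-identical output.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 2, chrom_len = 5e6,
                       n_blocks_per_chrom = 25,
                       block_len_range = c(2000, 10000),
                       snps_per_block_range = c(3, 8),
                       crossover_rate = 1, n_progeny = 5,
                       n_panel_extra = 12,
                       sweep_region = list(chrom = "A01", start = 2400001,
                                           end = 2500000),
                       sweep_freq_delta = 0.8, sweep_pi_reduction = 5,
                       sweep_snp_spacing = 2000,
                       snp_background_spacing = 10000,
                       intra_block_crossovers = FALSE, seed = 1) {
  cfg <- list(n_chrom = as.integer(n_chrom), chrom_len = as.integer(chrom_len),
              n_blocks_per_chrom = as.integer(n_blocks_per_chrom),
              block_len_range = as.integer(block_len_range),
              snps_per_block_range = as.integer(snps_per_block_range),
              crossover_rate = crossover_rate,
              n_progeny = as.integer(n_progeny),
              n_panel_extra = as.integer(n_panel_extra),
              sweep_region = sweep_region,
              sweep_freq_delta = sweep_freq_delta,
              sweep_pi_reduction = sweep_pi_reduction,
              sweep_snp_spacing = as.integer(sweep_snp_spacing),
              snp_background_spacing = snp_background_spacing,
              intra_block_crossovers = isTRUE(intra_block_crossovers),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_chrom >= 1, chrom_len >= 1, n_blocks_per_chrom >= 1,
              n_progeny >= 1, n_panel_extra >= 2, crossover_rate >= 0,
              sweep_freq_delta >= 0, sweep_freq_delta <= 1,
              sweep_pi_reduction >= 1,
              snps_per_block_range[1] >= 2)
    if (n_blocks_per_chrom * (block_len_range[2] + 200) > chrom_len)
      hb_stop("block intervals cannot fit on the chromosome",
              "hb_config_error")
  })
  if (!is.null(cfg$sweep_region)) {
    sr <- cfg$sweep_region
    stopifnot(sr$start >= 1, sr$end <= cfg$chrom_len, sr$start <= sr$end)
  }
  structure(cfg, class = "sim_config")
}

chrom_names <- function(n) {
  idx <- seq_len(n)
  ifelse(idx %% 2 == 1, sprintf("A%02d", (idx + 1) %/% 2),
         sprintf("D%02d", idx %/% 2))
}

## group-specific sweep allele frequencies (tolerant p_t, sensitive p_s):
## p_s - p_t = delta and p_t(1-p_t) = p_s(1-p_s)/reduction, so the tolerant
## group has both a shifted frequency and `reduction`-fold lower expected
## heterozygosity.
sweep_freqs <- function(delta, reduction) {
  if (delta == 0) return(c(tolerant = 0.5, sensitive = 0.5))
  if (reduction == 1) {
    pt <- (1 - delta) / 2
  } else {
    a <- 1 - reduction
    b <- reduction - 1 + 2 * delta
    cc <- -delta * (1 - delta)
    roots <- (-b + c(1, -1) * sqrt(b^2 - 4 * a * cc)) / (2 * a)
    pt <- roots[roots >= 0 & roots <= 1 - delta][1]
  }
  c(tolerant = pt, sensitive = pt + delta)
}

## lay n non-overlapping block intervals of lengths in len_range into
## [lo, hi] with >= min_gap bp between them (and to the span ends)
place_in_span <- function(lo, hi, n, len_range, min_gap = 200) {
  if (n == 0) return(NULL)
  lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  slack <- (hi - lo + 1) - sum(lens) - (n + 1) * min_gap
  if (slack < 0) hb_stop("block intervals exceed available span",
                         "hb_config_error")
  cuts <- sort(stats::runif(n, 0, 1))
  gaps <- min_gap + floor(diff(c(0, cuts, 1)) * slack)
  starts <- integer(n)
  at <- lo
  for (i in seq_len(n)) {
    at <- at + gaps[i]
    starts[i] <- at
    at <- at + lens[i]
  }
  data.frame(start = starts, end = starts + lens - 1)
}

## Poisson crossovers for one meiosis; optionally snapped to gap midpoints
draw_crossovers <- function(rate, chrom_len, gap_mids = NULL) {
  k <- stats::rpois(1, rate)
  if (k == 0) return(numeric(0))
  x <- sort(stats::runif(k, 1, chrom_len))
  if (!is.null(gap_mids) && length(gap_mids) > 0) {
    x <- vapply(x, function(p) gap_mids[which.min(abs(gap_mids - p))], 0)
  }
  x
}

## founder phase (1 = first parent, 2 = second) at each site position
phase_at <- function(pos, xpos, start_parent) {
  k <- findInterval(pos, sort(xpos))
  ifelse(k %% 2 == 0, start_parent, 3 - start_parent)
}

#' Simulate a pedigree panel with ground truth
#'
#' Builds the full panel: two founder parents and `n_panel_extra` unrelated
#' elite lines draw, per planted block, one of two complementary founder
#' haplotypes (assigned to exactly half of the founder lines, so every
#' planted SNP segregates at common frequency); the focal cultivar is a
#' fixed recombinant gamete of parentA x parentB per chromosome (crossover
#' count ~ Poisson(`crossover_rate`), positions uniform, snapped to
#' inter-block gaps unless `intra_block_crossovers`); each progeny line is
#' a fixed gamete of the focal cultivar x one unrelated elite co-parent,
#' with independent meioses. Sweep-region sites segregate independently
#' with group-specific allele frequencies (see [sim_config()]). Gene models
#' are tiled uniformly along every chromosome.
#'
#' @param config a [sim_config].
#' @return a list of class `hb_sim` with elements `geno`
#'   ([genotype_matrix]), `pedigree` ([pedigree_spec]), `groups` (named
#'   list with one [group_spec], trait `"tolerance"`, over the elite
#'   lines), `genes` ([gene_annotation]), `truth` (list: `blocks` with
#'   per-block focal/progeny origins, `pool` haplotypes per block,
#'   `crossovers`, `coparents`, `sweep`) and `config`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- chrom_names(config$n_chrom)
  elites <- sprintf("elite%02d", seq_len(config$n_panel_extra))
  progeny <- sprintf("progeny%d", seq_len(config$n_progeny))
  samples <- c("parentA", "parentB", "focal", progeny, elites)
  founders <- c("parentA", "parentB", elites)
  nf <- length(founders)

  ped <- pedigree_spec("parentA", "parentB", "focal", progeny)
  groups <- NULL
  if (config$n_panel_extra >= 4) {
    half <- config$n_panel_extra %/% 2
    groups <- list(tolerance = group_spec("tolerance",
                                          tolerant = elites[seq_len(half)],
                                          sensitive = elites[(half + 1):config$n_panel_extra]))
  }
  coparents <- setNames(sample(elites, config$n_progeny, replace = TRUE),
                        progeny)
  pf <- sweep_freqs(config$sweep_freq_delta, config$sweep_pi_reduction)

  all_chrom <- character(0); all_pos <- integer(0)
  all_ref <- character(0); all_alt <- character(0)
  allele_rows <- list()
  truth_blocks <- list(); truth_x <- list(); pool_list <- list()
  genes_list <- list()
  bid <- 0L

  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    sweep_here <- !is.null(config$sweep_region) &&
      config$sweep_region$chrom == ch
    ## block placement, avoiding the sweep region
    if (sweep_here) {
      sr <- config$sweep_region
      spans <- list(c(1, sr$start - 1), c(sr$end + 1, config$chrom_len))
      spans <- Filter(function(s) s[2] - s[1] > config$block_len_range[2] + 400,
                      spans)
      w <- vapply(spans, function(s) s[2] - s[1] + 1, 0)
      n_per <- floor(config$n_blocks_per_chrom * w / sum(w))
      n_per[1] <- config$n_blocks_per_chrom - sum(n_per[-1])
    } else {
      spans <- list(c(1, config$chrom_len))
      n_per <- config$n_blocks_per_chrom
    }
    iv <- do.call(rbind, Map(function(s, n)
      place_in_span(s[1], s[2], n, config$block_len_range), spans, n_per))
    iv <- iv[order(iv$start), , drop = FALSE]

    ## per-block SNP positions and balanced founder haplotype pools
    site_pos <- integer(0); site_block <- integer(0)
    founder_alleles <- NULL
    blk_rows <- list()
    for (b in seq_len(nrow(iv))) {
      bid <- bid + 1L
      k <- sample(seq(config$snps_per_block_range[1],
                      config$snps_per_block_range[2]), 1)
      span <- iv$start[b]:iv$end[b]
      inner <- if (k > 2 && length(span) > 2)
        sort(sample(span[-c(1, length(span))], k - 2)) else integer(0)
      pos_b <- c(iv$start[b], inner, iv$end[b])
      h1 <- stats::rbinom(k, 1, 0.5)
      h2 <- 1L - h1
      assign <- sample(rep(1:2, length.out = nf))  # balanced pool split
      fa <- vapply(seq_len(nf),
                   function(j) if (assign[j] == 1) h1 else h2,
                   integer(k))
      site_pos <- c(site_pos, pos_b)
      site_block <- c(site_block, rep(bid, k))
      founder_alleles <- rbind(founder_alleles, fa)
      pool_list[[bid]] <- list(h1 = h1, h2 = h2, assign = setNames(assign, founders))
      blk_rows[[b]] <- data.frame(block_id = bid, chrom = ch,
                                  start = iv$start[b], end = iv$end[b],
                                  n_snps = k)
    }
    ## sweep-region sites: independent, group-differentiated
    if (sweep_here) {
      sr <- config$sweep_region
      spos <- seq(sr$start + config$sweep_snp_spacing %/% 2, sr$end,
                  by = config$sweep_snp_spacing)
      if (length(spos) > 0) {
        freq <- setNames(rep(pf["sensitive"], nf), founders)
        if (!is.null(groups)) freq[groups$tolerance$tolerant] <- pf["tolerant"]
        sa <- vapply(seq_len(nf),
                     function(j) stats::rbinom(length(spos), 1, freq[j]),
                     integer(length(spos)))
        site_pos <- c(site_pos, spos)
        site_block <- c(site_block, rep(NA_integer_, length(spos)))
        founder_alleles <- rbind(founder_alleles, sa)
      }
    }
    ## background SNPs in inter-block gaps, independently segregating
    if (is.finite(config$snp_background_spacing)) {
      bpos <- seq(1000, config$chrom_len - 1000,
                  by = config$snp_background_spacing)
      in_block <- vapply(bpos, function(p)
        any(p >= iv$start & p <= iv$end), TRUE)
      if (sweep_here)
        in_block <- in_block | (bpos >= config$sweep_region$start &
                                bpos <= config$sweep_region$end)
      bpos <- bpos[!in_block & !(bpos %in% site_pos)]
      if (length(bpos) > 0) {
        bfreq <- stats::runif(length(bpos), 0.1, 0.9)
        ba <- vapply(seq_len(nf),
                     function(j) stats::rbinom(length(bpos), 1, bfreq),
                     integer(length(bpos)))
        site_pos <- c(site_pos, bpos)
        site_block <- c(site_block, rep(NA_integer_, length(bpos)))
        founder_alleles <- rbind(founder_alleles, ba)
      }
    }
    ord <- order(site_pos)
    site_pos <- site_pos[ord]
    site_block <- site_block[ord]
    founder_alleles <- founder_alleles[ord, , drop = FALSE]
    colnames(founder_alleles) <- founders

    ## inter-block gap midpoints for crossover snapping
    gap_mids <- NULL
    if (!config$intra_block_crossovers) {
      nb <- nrow(iv)
      between <- if (nb > 1) (iv$end[-nb] + iv$start[-1]) / 2 else numeric(0)
      gap_mids <- c((1 + iv$start[1]) / 2, between,
                    (iv$end[nb] + config$chrom_len) / 2)
    }

    ## focal meiosis (parentA x parentB), then fixed to homozygosity
    fx <- draw_crossovers(config$crossover_rate, config$chrom_len, gap_mids)
    f_start <- sample(1:2, 1)
    f_phase <- phase_at(site_pos, fx, f_start)
    focal_al <- ifelse(f_phase == 1, founder_alleles[, "parentA"],
                       founder_alleles[, "parentB"])
    if (length(fx) > 0)
      truth_x[[length(truth_x) + 1]] <- data.frame(sample = "focal",
                                                   chrom = ch, pos = fx)

    ## progeny meioses (focal x co-parent)
    prog_al <- matrix(0L, length(site_pos), config$n_progeny,
                      dimnames = list(NULL, progeny))
    p_phase <- matrix(0L, length(site_pos), config$n_progeny)
    for (j in seq_len(config$n_progeny)) {
      px <- draw_crossovers(config$crossover_rate, config$chrom_len, gap_mids)
      p_start <- sample(1:2, 1)
      ph <- phase_at(site_pos, px, p_start)   # 1 = focal, 2 = co-parent
      prog_al[, j] <- ifelse(ph == 1, focal_al,
                             founder_alleles[, coparents[progeny[j]]])
      p_phase[, j] <- ph
      if (length(px) > 0)
        truth_x[[length(truth_x) + 1]] <- data.frame(sample = progeny[j],
                                                     chrom = ch, pos = px)
    }

    ## per-block origin bookkeeping (single label, or "mosaic" if a
    ## crossover landed inside the block)
    blk <- do.call(rbind, blk_rows)
    blk$focal_origin <- vapply(seq_len(nrow(blk)), function(b) {
      idx <- which(site_block == blk$block_id[b])
      ph <- unique(f_phase[idx])
      if (length(ph) > 1) "mosaic" else c("parentA", "parentB")[ph]
    }, character(1))
    for (j in seq_len(config$n_progeny)) {
      blk[[paste0("origin_", progeny[j])]] <-
        vapply(seq_len(nrow(blk)), function(b) {
          idx <- which(site_block == blk$block_id[b])
          ph <- unique(p_phase[idx, j])
          if (length(ph) > 1) "mosaic" else c("focal", "coparent")[ph]
        }, character(1))
    }
    truth_blocks[[ci]] <- blk

    alleles_ch <- cbind(founder_alleles[, "parentA", drop = FALSE],
                        founder_alleles[, "parentB", drop = FALSE],
                        focal = focal_al, prog_al,
                        founder_alleles[, elites, drop = FALSE])
    colnames(alleles_ch) <- samples
    allele_rows[[ci]] <- alleles_ch
    all_chrom <- c(all_chrom, rep(ch, length(site_pos)))
    all_pos <- c(all_pos, site_pos)
    ra <- matrix(sample(c("A", "C", "G", "T"), 2 * length(site_pos),
                        replace = TRUE), ncol = 2)
    same <- ra[, 1] == ra[, 2]
    ra[same, 2] <- chartr("ACGT", "CGTA", ra[same, 1])
    all_ref <- c(all_ref, ra[, 1]); all_alt <- c(all_alt, ra[, 2])

    ## tiled gene models
    gs <- seq(5001, config$chrom_len - 3000, by = 20000)
    genes_list[[ci]] <- gene_annotation(
      gene_id = sprintf("%s_g%03d", ch, seq_along(gs)),
      chrom = rep(ch, length(gs)), start = gs, end = gs + 2999,
      strand = rep(c("+", "-"), length.out = length(gs)))
  }

  geno <- genotype_matrix(all_chrom, all_pos, all_ref, all_alt,
                          do.call(rbind, allele_rows), samples)
  truth <- list(
    blocks = do.call(rbind, truth_blocks),
    pool = pool_list,
    crossovers = if (length(truth_x)) do.call(rbind, truth_x) else
      data.frame(sample = character(0), chrom = character(0),
                 pos = numeric(0)),
    coparents = coparents,
    sweep = if (is.null(config$sweep_region)) NULL else
      as.data.frame(config$sweep_region))
  genes <- do.call(rbind, genes_list)
  class(genes) <- c("gene_annotation", "data.frame")
  structure(list(geno = geno, pedigree = ped, groups = groups,
                 genes = genes, truth = truth, config = config),
            class = "hb_sim")
}

#' @export
print.hb_sim <- function(x, ...) {
  cat(sprintf("hb_sim: %d samples, %d sites, %d planted blocks, seed %d\n",
              length(x$geno$sample_ids), n_sites(x$geno),
              nrow(x$truth$blocks), x$config$seed))
  invisible(x)
}

#' Write a simulated panel to disk
#'
#' Emits `panel.vcf`, `genes.gff3`, `metadata.tsv` and the truth tables
#' (`truth_blocks.tsv`, `truth_crossovers.tsv`, `truth_sweep.tsv`).
#'
#' @param sim an `hb_sim` from [simulate_panel()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_panel <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "panel.vcf"),
             gff = file.path(dir, "genes.gff3"),
             metadata = file.path(dir, "metadata.tsv"),
             truth_blocks = file.path(dir, "truth_blocks.tsv"),
             truth_crossovers = file.path(dir, "truth_crossovers.tsv"),
             truth_sweep = file.path(dir, "truth_sweep.tsv"))
  write_vcf(sim$geno, paths["vcf"])
  write_gff(sim$genes, paths["gff"])
  write_metadata(sim$pedigree, sim$groups, sim$geno$sample_ids,
                 paths["metadata"])
  utils::write.table(sim$truth$blocks, paths["truth_blocks"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$crossovers, paths["truth_crossovers"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sim$truth$sweep))
    utils::write.table(sim$truth$sweep, paths["truth_sweep"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(paths)
}
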