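## Candidate-gene mapping: intersect sweep regions and haplotype blocks
## with gene models, and aggregate per-trait candidate-gene sets.

#' Genes overlapping a genomic interval
#'
#' @param genes a [gene_annotation] table.
#' @param chrom chromosome.
#' @param start,end 1-based inclusive query interval (`start <= end`).
#' @param min_overlap minimum overlap in bp (default 1).
#' @return character vector of overlapping `gene_id`s (annotation order).
#' @export
genes_in_interval <- function(genes, chrom, start, end, min_overlap = 1) {
  if (start > end) hb_stop("interval start > end", "hb_invalid")
  on_chr <- genes$chrom == chrom
  if (!any(on_chr)) return(character(0))
  g <- genes[on_chr, ]
  hits <- IRanges::findOverlaps(IRanges::IRanges(start, end),
                                IRanges::IRanges(g$start, g$end),
                                minoverlap = min_overlap)
  g$gene_id[sort(S4Vectors::subjectHits(hits))]
}

#' Aggregate candidate genes and trait-linked blocks
#'
#' For each trait: the unique genes overlapped by that trait's sweep
#' regions (the candidate-gene set), and the haplotype blocks overlapping
#' at least one of those candidate genes (trait-linked blocks). Per-trait
#' counts may share genes/blocks across traits; the union is also
#' reported, alongside the duplicate-counting sum of the per-trait
#' counts.
#'
#' @param regions_by_trait named list of `sweep_regions` data.frames (one
#'   per trait; columns `chrom`, `start`, `end`).
#' @param blocks a `haplotype_blocks` list (or its data.frame), or `NULL`
#'   to skip block linkage.
#' @param genes a [gene_annotation] table.
#' @param min_overlap minimum overlap in bp for gene membership.
#' @return list of class `candidate_genes` with `genes` (data.frame
#'   `trait`, `gene_id`, `source_region`), `blocks` (data.frame `trait`,
#'   `block_id`, `gene_id`), `per_trait_gene_counts`, `gene_total_sum`,
#'   `gene_total_union`, `per_trait_block_counts`, `block_total_sum`,
#'   `block_total_union`.
#' @export
aggregate_candidates <- function(regions_by_trait, blocks, genes,
                                 min_overlap = 1) {
  bad <- unique(unlist(lapply(regions_by_trait, function(r)
    setdiff(r$chrom, genes$chrom))))
  if (length(bad) > 0)
    hb_stop(sprintf("chromosomes absent from annotation: %s",
                    paste(bad, collapse = ", ")), "hb_invalid")
  blk_df <- if (is.null(blocks)) NULL else
    if (is.data.frame(blocks)) blocks else as.data.frame(blocks)

  gene_rows <- list(); blk_rows <- list()
  for (tr in names(regions_by_trait)) {
    regs <- regions_by_trait[[tr]]
    for (i in seq_len(nrow(regs))) {
      ids <- genes_in_interval(genes, regs$chrom[i], regs$start[i],
                               regs$end[i], min_overlap)
      if (length(ids) > 0)
        gene_rows[[length(gene_rows) + 1]] <- data.frame(
          trait = tr, gene_id = ids,
          source_region = sprintf("%s:%d-%d", regs$chrom[i],
                                  regs$start[i], regs$end[i]),
          stringsAsFactors = FALSE)
    }
    trait_genes <- unique(unlist(lapply(gene_rows, function(r)
      r$gene_id[r$trait == tr])))
    if (!is.null(blk_df) && length(trait_genes) > 0) {
      g <- genes[genes$gene_id %in% trait_genes, ]
      for (j in seq_len(nrow(blk_df))) {
        hit <- genes_in_interval(g, blk_df$chrom[j], blk_df$start[j],
                                 blk_df$end[j], min_overlap)
        if (length(hit) > 0)
          blk_rows[[length(blk_rows) + 1]] <- data.frame(
            trait = tr, block_id = blk_df$block_id[j],
            gene_id = paste(hit, collapse = ";"),
            stringsAsFactors = FALSE)
      }
    }
  }
  gene_df <- if (length(gene_rows)) unique(do.call(rbind, gene_rows)) else
    data.frame(trait = character(0), gene_id = character(0),
               source_region = character(0), stringsAsFactors = FALSE)
  blk_out <- if (length(blk_rows)) do.call(rbind, blk_rows) else
    data.frame(trait = character(0), block_id = character(0),
               gene_id = character(0), stringsAsFactors = FALSE)
  per_gene <- vapply(names(regions_by_trait), function(tr)
    length(unique(gene_df$gene_id[gene_df$trait == tr])), 0L)
  per_blk <- vapply(names(regions_by_trait), function(tr)
    length(unique(blk_out$block_id[blk_out$trait == tr])), 0L)
  structure(list(genes = gene_df, blocks = blk_out,
                 per_trait_gene_counts = per_gene,
                 gene_total_sum = sum(per_gene),
                 gene_total_union = length(unique(gene_df$gene_id)),
                 per_trait_block_counts = per_blk,
                 block_total_sum = sum(per_blk),
                 block_total_union = length(unique(blk_out$block_id))),
            class = "candidate_genes")
}

#' @export
print.candidate_genes <- function(x, ...) {
  cat("candidate_genes\n  genes per trait: ",
      paste(sprintf("%s=%d", names(x$per_trait_gene_counts),
                    x$per_trait_gene_counts), collapse = ", "),
      sprintf("\n  sum %d, union %d\n", x$gene_total_sum,
              x$gene_total_union))
  if (nrow(x$blocks) > 0 || x$block_total_sum > 0)
    cat("  trait-linked blocks: ",
        paste(sprintf("%s=%d", names(x$per_trait_block_counts),
                      x$per_trait_block_counts), collapse = ", "),
        sprintf("\n  sum %d, union %d\n", x$block_total_sum,
                x$block_total_union))
  invisible(x)
}
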