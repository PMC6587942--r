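## End-to-end orchestration: simulate (or read) -> filter -> blocks ->
## sweep scan -> pedigree classification -> gene annotation -> report,
## with every intermediate written to disk and a JSON manifest.

#' Pipeline configuration
#'
#' Either `sim` (a [sim_config], the panel is simulated) or the three
#' input paths (`vcf`, `gff`, `metadata`) must be given.
#'
#' @param out_dir output directory.
#' @param sim optional [sim_config].
#' @param vcf,gff,metadata optional input files (used when `sim` is
#'   `NULL`).
#' @param maf_min,max_missing site filters for [read_vcf()].
#' @param cu_min,cl_min,dprime_break strong-LD thresholds for
#'   [partition_blocks()].
#' @param win_size,step,tail sweep-scan parameters (defaults 100 kb,
#'   10 kb, top 1%).
#' @param seed integer seed for any stochastic stage.
#' @return a list of class `run_config`.
#' @export
run_config <- function(out_dir, sim = NULL, vcf = NULL, gff = NULL,
                       metadata = NULL, maf_min = 0.05, max_missing = 0.2,
                       cu_min = 0.98, cl_min = 0.7, dprime_break = 0.7,
                       win_size = 1e5, step = 1e4, tail = 0.01, seed = 1) {
  if (is.null(sim) && (is.null(vcf) || is.null(metadata)))
    hb_stop("need either a sim config or vcf+metadata paths",
            "hb_config_error")
  stopifnot(maf_min >= 0, maf_min < 0.5, max_missing >= 0,
            max_missing <= 1, cu_min > 0, cu_min <= 1, cl_min >= 0,
            cl_min <= 1, win_size >= 1, step >= 1, tail > 0, tail <= 1)
  structure(list(out_dir = out_dir, sim = sim, vcf = vcf, gff = gff,
                 metadata = metadata, maf_min = maf_min,
                 max_missing = max_missing, cu_min = cu_min,
                 cl_min = cl_min, dprime_break = dprime_break,
                 win_size = win_size, step = step, tail = tail,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order, writing every intermediate artifact under
#' `config$out_dir` and a `manifest.json` with input checksums, parameter
#' values, package version and per-stage record counts. Identical
#' configuration and seed give byte-identical outputs. A stage failure
#' aborts with the stage name; outputs written so far are retained and a
#' `.partial` marker file is left in the output directory.
#'
#' @param config a [run_config].
#' @param verbose log per-stage progress.
#' @return invisibly, a list with the in-memory stage results (`geno`,
#'   `blocks`, `scan`, `regions`, `classifications`, `report`, `tally`,
#'   `candidates`, `manifest`).
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  partial <- file.path(config$out_dir, ".partial")
  file.create(partial)
  stage <- "init"
  manifest <- list(package = "hapblocks",
                   version = as.character(utils::packageVersion("hapblocks")),
                   parameters = config[setdiff(names(config),
                                               c("sim", "out_dir"))],
                   stages = list())
  result <- list()
  tryCatch({
    ## stage 1: obtain inputs
    stage <- "simulate"
    if (!is.null(config$sim)) {
      sim <- simulate_panel(config$sim)
      paths <- write_panel(sim, file.path(config$out_dir, "sim"))
      vcf_path <- paths[["vcf"]]; gff_path <- paths[["gff"]]
      md_path <- paths[["metadata"]]
      msg_log(verbose, "[simulate] %d sites, %d samples",
              n_sites(sim$geno), length(sim$geno$sample_ids))
    } else {
      vcf_path <- config$vcf; gff_path <- config$gff
      md_path <- config$metadata
    }
    manifest$inputs <- list(vcf = unname(tools::md5sum(vcf_path)),
                            gff = if (!is.null(gff_path))
                              unname(tools::md5sum(gff_path)) else NULL,
                            metadata = unname(tools::md5sum(md_path)))

    ## stage 2: read + filter
    stage <- "read"
    geno <- read_vcf(vcf_path, maf_min = config$maf_min,
                     max_missing = config$max_missing, verbose = verbose)
    md <- read_metadata(md_path)
    genes <- if (!is.null(gff_path)) read_gff(gff_path) else NULL
    manifest$stages$read <- list(n_sites = n_sites(geno),
                                 n_samples = length(geno$sample_ids))
    msg_log(verbose, "[read] %d sites pass filters", n_sites(geno))

    ## stage 3: haplotype blocks
    stage <- "blocks"
    blocks <- partition_blocks(geno, cu_min = config$cu_min,
                               cl_min = config$cl_min,
                               dprime_break = config$dprime_break)
    write_blocks(blocks, file.path(config$out_dir, "blocks.tsv"),
                 file.path(config$out_dir, "block_haplotypes.tsv"))
    manifest$stages$blocks <- list(n_blocks = length(blocks))
    msg_log(verbose, "[blocks] %d blocks", length(blocks))

    ## stage 4: sweep scan per trait
    stage <- "scan"
    regions_by_trait <- list()
    scan_stats <- list()
    for (tr in names(md$groups)) {
      st <- sweep_scan(geno, md$groups[[tr]], win_size = config$win_size,
                       step = config$step)
      rg <- select_candidates(st, tail = config$tail)
      scan_stats[[tr]] <- st
      regions_by_trait[[tr]] <- rg
      write_window_stats(st, file.path(config$out_dir,
                                       sprintf("windows_%s.tsv", tr)))
      write_sweep_regions(rg, file.path(config$out_dir,
                                        sprintf("sweeps_%s.bed", tr)))
      msg_log(verbose, "[scan] %s: %d windows, %d candidate region(s)",
              tr, nrow(st), nrow(rg))
    }
    manifest$stages$scan <- lapply(regions_by_trait, nrow)

    ## stage 5: pedigree classification
    stage <- "classify"
    classifications <- NULL; report <- NULL; tally <- NULL
    if (!is.null(md$pedigree) && length(blocks) > 0) {
      classifications <- classify_blocks(blocks, md$pedigree)
      report <- family_report(classifications)
      tally <- subgenome_tally(blocks)
      write_classifications(classifications,
                            file.path(config$out_dir,
                                      "block_classifications.tsv"))
      write_family_report(report, file.path(config$out_dir,
                                            "family_report.tsv"))
      utils::write.table(tally, file.path(config$out_dir,
                                          "subgenome_tally.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$stages$classify <- as.list(report$counts)
      msg_log(verbose, "[classify] %s",
              paste(sprintf("%s=%d", names(report$counts), report$counts),
                    collapse = " "))
    }

    ## stage 6: candidate genes
    stage <- "annotate"
    candidates <- NULL
    if (!is.null(genes) && length(regions_by_trait) > 0) {
      candidates <- aggregate_candidates(regions_by_trait, blocks, genes)
      utils::write.table(candidates$genes,
                         file.path(config$out_dir, "candidate_genes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(candidates$blocks,
                         file.path(config$out_dir,
                                   "trait_linked_blocks.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$stages$annotate <-
        list(genes_union = candidates$gene_total_union,
             blocks_union = candidates$block_total_union)
      msg_log(verbose, "[annotate] %d candidate gene(s) in union",
              candidates$gene_total_union)
    }

    stage <- "manifest"
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
    file.remove(partial)
    result <- list(geno = geno, blocks = blocks, scan = scan_stats,
                   regions = regions_by_trait,
                   classifications = classifications, report = report,
                   tally = tally, candidates = candidates,
                   manifest = manifest)
  }, error = function(e) {
    hb_stop(sprintf("pipeline stage '%s' failed: %s", stage,
                    conditionMessage(e)), "hb_stage_error")
  })
  invisible(result)
}
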