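## Standard-format input/output: VCF genotypes, GFF3 genes, metadata TSV.
## VCF parsing is delegated to vcfR; GFF3 to rtracklayer.

#' Read a multi-sample VCF into a genotype matrix
#'
#' Reads a VCF of biallelic SNPs called on near-homozygous lines and builds
#' the internal haploid-coded [genotype_matrix]. Genotypes `0/0` (or `0`)
#' code 0, `1/1` (or `1`) code 1, and missing genotypes code -1.
#' Residual heterozygous calls are treated as noise rather than phased:
#' they are recoded missing (-1) and the per-sample heterozygosity rate is
#' reported when `verbose = TRUE`. Multiallelic records are skipped with a
#' logged count.
#'
#' @param path VCF file (plain or gzipped).
#' @param maf_min minimum minor-allele frequency (computed over non-missing
#'   haploid calls); sites below are dropped. Default 0.05.
#' @param max_missing maximum fraction of missing calls per site. Default
#'   0.2.
#' @param verbose log filter and heterozygosity summaries.
#' @return a [genotype_matrix], sites sorted by (chromosome, position).
#' @export
read_vcf <- function(path, maf_min = 0.05, max_missing = 0.2,
                     verbose = FALSE) {
  if (!file.exists(path)) hb_stop(sprintf("no such file: %s", path),
                                  "hb_io_error")
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e)
                  hb_stop(sprintf("malformed VCF '%s': %s", path,
                                  conditionMessage(e)), "hb_parse_error"))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0)
    hb_stop("VCF contains no variant records", "hb_empty_matrix")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  samples <- colnames(v@gt)[-1]
  colnames(gt) <- samples

  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  biallelic <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    nchar(ref) == 1 & nchar(alt) == 1
  n_multi <- sum(!biallelic)
  if (n_multi > 0)
    msg_log(verbose, "read_vcf: skipped %d non-biallelic-SNP record(s)",
            n_multi)
  if (!any(biallelic))
    hb_stop("no biallelic SNP records in VCF", "hb_empty_matrix")
  fix <- fix[biallelic, , drop = FALSE]
  gt <- gt[biallelic, , drop = FALSE]

  ## strip phasing, collapse to haploid codes
  gt[is.na(gt)] <- "."
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code <- matrix(-1L, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  code[gt %in% c("0", "0/0")] <- 0L
  code[gt %in% c("1", "1/1")] <- 1L
  het <- gt %in% c("0/1", "1/0")
  if (any(het)) {
    het_rate <- colMeans(matrix(het, nrow(gt)))
    names(het_rate) <- colnames(gt)
    msg_log(verbose,
            "read_vcf: recoded %d heterozygous call(s) as missing (max per-sample het rate %.3f)",
            sum(het), max(het_rate))
  }

  m <- genotype_matrix(chrom = fix[, "CHROM"],
                       pos = as.integer(as.numeric(fix[, "POS"])),
                       ref = fix[, "REF"], alt = fix[, "ALT"],
                       alleles = code, sample_ids = samples)
  ord <- order(m$chrom, m$pos)
  m <- subset_sites(m, ord)
  filter_sites(m, maf_min = maf_min, max_missing = max_missing,
               verbose = verbose)
}

#' Filter sites of a genotype matrix by MAF and missingness
#'
#' @param m a [genotype_matrix].
#' @inheritParams read_vcf
#' @return the filtered [genotype_matrix]. Raising `maf_min` or lowering
#'   `max_missing` never increases the retained site count.
#' @export
filter_sites <- function(m, maf_min = 0.05, max_missing = 0.2,
                         verbose = FALSE) {
  if (n_sites(m) == 0)
    hb_stop("all sites filtered out (empty matrix)", "hb_empty_matrix")
  al <- m$alleles
  n_miss <- rowSums(al == -1L)
  n_obs <- ncol(al) - n_miss
  n_alt <- rowSums(al == 1L)
  f <- ifelse(n_obs > 0, n_alt / n_obs, 0)
  maf <- pmin(f, 1 - f)
  keep <- maf >= maf_min & (n_miss / ncol(al)) <= max_missing & n_obs > 0
  msg_log(verbose, "filter_sites: kept %d of %d sites (maf >= %g, missing <= %g)",
          sum(keep), length(keep), maf_min, max_missing)
  if (!any(keep))
    hb_stop("all sites filtered out (empty matrix)", "hb_empty_matrix")
  subset_sites(m, keep)
}

#' Write a genotype matrix as VCF 4.2
#'
#' Haploid-coded alleles are written as homozygous diploid genotypes
#' (`0/0`, `1/1`, missing `./.`), the convention used for inbred-line
#' panels, so the file round-trips through [read_vcf()] unchanged.
#'
#' @param m a [genotype_matrix] (must be coordinate-sorted).
#' @param path output file path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(m, path) {
  stopifnot(inherits(m, "genotype_matrix"))
  for (ch in unique(m$chrom)) {
    p <- m$pos[m$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      hb_stop("matrix is not coordinate-sorted", "hb_unsorted")
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=hapblocks",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", m$sample_ids), collapse = "\t"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(hdr, con)
  if (n_sites(m) > 0) {
    gt <- matrix("./.", n_sites(m), length(m$sample_ids))
    gt[m$alleles == 0L] <- "0/0"
    gt[m$alleles == 1L] <- "1/1"
    body <- paste(m$chrom, m$pos, ".", m$ref, m$alt, ".", "PASS", ".",
                  "GT", sep = "\t")
    body <- paste(body, apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Extracts `gene` features with their `ID` attribute; coordinates are kept
#' 1-based inclusive as in GFF3.
#'
#' @param path GFF3 file.
#' @return a `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (class `gene_annotation`); empty (with a warning) if the file
#'   has no gene features.
#' @export
read_gff <- function(path) {
  if (!file.exists(path)) hb_stop(sprintf("no such file: %s", path),
                                  "hb_io_error")
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  if (length(gr) == 0) {
    warning("no gene features in GFF")
    return(gene_annotation(character(0), character(0), integer(0),
                           integer(0), character(0)))
  }
  ids <- S4Vectors::mcols(gr)$ID
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    hb_stop("gene feature without ID attribute", "hb_parse_error")
  gene_annotation(gene_id = as.character(ids),
                  chrom = as.character(GenomicRanges::seqnames(gr)),
                  start = GenomicRanges::start(gr),
                  end = GenomicRanges::end(gr),
                  strand = as.character(GenomicRanges::strand(gr)))
}

#' Gene annotation table
#'
#' @param gene_id unique gene identifiers.
#' @param chrom chromosome per gene.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param strand `"+"`, `"-"` or `"*"`.
#' @return a `data.frame` of class `gene_annotation`.
#' @export
gene_annotation <- function(gene_id, chrom, start, end,
                            strand = rep("+", length(gene_id))) {
  strand[strand == "*"] <- "+"
  if (anyDuplicated(gene_id)) hb_stop("gene_id not unique", "hb_invalid")
  if (any(start > end)) hb_stop("gene with start > end", "hb_invalid")
  structure(data.frame(gene_id = as.character(gene_id),
                       chrom = as.character(chrom),
                       start = as.integer(start), end = as.integer(end),
                       strand = as.character(strand),
                       stringsAsFactors = FALSE),
            class = c("gene_annotation", "data.frame"))
}

#' Write gene models as GFF3
#'
#' @param genes a [gene_annotation] table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff <- function(genes, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes) > 0) {
    writeLines(paste(genes$chrom, "hapblocks", "gene", genes$start,
                     genes$end, ".", genes$strand, ".",
                     paste0("ID=", genes$gene_id), sep = "\t"), con)
  }
  invisible(path)
}

#' Pedigree specification
#'
#' Roles in the two-parent -> focal-cultivar -> progeny breeding design.
#'
#' @param parentA,parentB,focal single sample ids.
#' @param progeny character vector of progeny sample ids (>= 1).
#' @return a list of class `pedigree_spec`.
#' @export
pedigree_spec <- function(parentA, parentB, focal, progeny) {
  ids <- c(parentA, parentB, focal, progeny)
  if (anyDuplicated(ids))
    hb_stop("pedigree roles must be disjoint", "hb_invalid")
  if (length(progeny) < 1) hb_stop("need >= 1 progeny", "hb_invalid")
  structure(list(parentA = parentA, parentB = parentB, focal = focal,
                 progeny = as.character(progeny)),
            class = "pedigree_spec")
}

#' Family sample ids of a pedigree
#' @param ped a [pedigree_spec].
#' @return character vector: parents, focal, progeny.
#' @export
family_ids <- function(ped) {
  c(ped$parentA, ped$parentB, ped$focal, ped$progeny)
}

#' Trait-group specification
#'
#' @param trait trait label (e.g. `"V.wilt"`, `"salt"`, `"drought"`).
#' @param tolerant,sensitive disjoint sample-id vectors, each >= 2 samples.
#' @return a list of class `group_spec`.
#' @export
group_spec <- function(trait, tolerant, sensitive) {
  if (length(intersect(tolerant, sensitive)) > 0)
    hb_stop("tolerant and sensitive groups overlap", "hb_invalid")
  if (length(tolerant) < 2 || length(sensitive) < 2)
    hb_stop("each trait group needs >= 2 samples", "hb_invalid")
  structure(list(trait = trait, tolerant = as.character(tolerant),
                 sensitive = as.character(sensitive)),
            class = "group_spec")
}

#' Read sample metadata (pedigree roles and trait groups)
#'
#' Tab-separated file with columns `sample_id`, `role`, `trait`, `group`.
#' `role` is one of `parentA`, `parentB`, `focal`, `progeny`, `panel`;
#' trait membership rows carry `trait` and `group` (`tolerant`/`sensitive`),
#' one row per sample x trait, `.` for empty fields.
#'
#' @param path metadata TSV.
#' @return list with `pedigree` (a [pedigree_spec] or `NULL`) and `groups`
#'   (named list of [group_spec], one per trait).
#' @export
read_metadata <- function(path) {
  md <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "role", "trait", "group")
  if (!all(need %in% names(md)))
    hb_stop("metadata must have columns sample_id, role, trait, group",
            "hb_parse_error")
  roles <- unique(md[md$role != ".", c("sample_id", "role")])
  ped <- NULL
  if (all(c("parentA", "parentB", "focal") %in% roles$role) &&
      any(roles$role == "progeny")) {
    ped <- pedigree_spec(roles$sample_id[roles$role == "parentA"][1],
                         roles$sample_id[roles$role == "parentB"][1],
                         roles$sample_id[roles$role == "focal"][1],
                         roles$sample_id[roles$role == "progeny"])
  }
  groups <- list()
  for (tr in setdiff(unique(md$trait), ".")) {
    sub <- md[md$trait == tr, ]
    groups[[tr]] <- group_spec(tr,
                               tolerant = sub$sample_id[sub$group == "tolerant"],
                               sensitive = sub$sample_id[sub$group == "sensitive"])
  }
  list(pedigree = ped, groups = groups)
}

#' Write sample metadata TSV
#'
#' Inverse of [read_metadata()].
#'
#' @param pedigree a [pedigree_spec] or `NULL`.
#' @param groups named list of [group_spec].
#' @param sample_ids all panel sample ids (ensures every sample appears).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(pedigree, groups, sample_ids, path) {
  role <- setNames(rep("panel", length(sample_ids)), sample_ids)
  if (!is.null(pedigree)) {
    role[pedigree$parentA] <- "parentA"
    role[pedigree$parentB] <- "parentB"
    role[pedigree$focal] <- "focal"
    role[pedigree$progeny] <- "progeny"
  }
  rows <- data.frame(sample_id = sample_ids, role = unname(role[sample_ids]),
                     trait = ".", group = ".", stringsAsFactors = FALSE)
  for (g in groups) {
    rows <- rbind(rows,
                  data.frame(sample_id = g$tolerant, role = ".",
                             trait = g$trait, group = "tolerant",
                             stringsAsFactors = FALSE),
                  data.frame(sample_id = g$sensitive, role = ".",
                             trait = g$trait, group = "sensitive",
                             stringsAsFactors = FALSE))
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
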