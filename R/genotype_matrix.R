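#' Construct a genotype matrix for haploid-coded inbred lines
#'
#' The central container of the package: biallelic SNP alleles for S sites
#' by N samples. Because the lines are near-fully homozygous (inbred or
#' allohaploid derivatives), each sample contributes a single haplotype per
#' locus and genotypes are coded haploid: `0` = reference allele, `1` =
#' alternate allele, `-1` = missing (including residual heterozygous calls,
#' see [read_vcf()]).
#'
#' @param chrom character vector of chromosome labels, one per site.
#' @param pos integer vector of 1-based physical positions (bp), strictly
#'   increasing within each chromosome.
#' @param ref,alt single-character allele symbols per site.
#' @param alleles integer matrix, sites x samples, values in `{0, 1, -1}`.
#' @param sample_ids unique sample labels (column names of `alleles`).
#' @return an object of class `genotype_matrix`: a list with elements
#'   `chrom`, `pos`, `ref`, `alt`, `alleles`, `sample_ids`.
#' @seealso [read_vcf()], [write_vcf()], [simulate_panel()]
#' @export
genotype_matrix <- function(chrom, pos, ref, alt, alleles, sample_ids) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  n_site <- length(chrom)
  stopifnot(length(pos) == n_site, length(ref) == n_site,
            length(alt) == n_site, nrow(alleles) == n_site,
            ncol(alleles) == length(sample_ids))
  if (anyDuplicated(sample_ids))
    hb_stop("sample_ids must be unique", "hb_invalid_matrix")
  if (!all(alleles %in% c(-1L, 0L, 1L)))
    hb_stop("allele codes must be in {0, 1, -1}", "hb_invalid_matrix")
  pos <- as.integer(pos)
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      hb_stop(sprintf("positions not strictly increasing on %s", ch),
              "hb_unsorted")
  }
  colnames(alleles) <- sample_ids
  structure(list(chrom = as.character(chrom), pos = pos,
                 ref = as.character(ref), alt = as.character(alt),
                 alleles = alleles, sample_ids = as.character(sample_ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d samples over %d chromosome(s)\n",
              n_sites(x), length(x$sample_ids), length(unique(x$chrom))))
  miss <- if (n_sites(x)) mean(x$alleles == -1L) else 0
  cat(sprintf("  missingness: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Number of sites in a genotype matrix
#' @param x a [genotype_matrix].
#' @return integer site count.
#' @export
n_sites <- function(x) length(x$pos)

#' Subset sites of a genotype matrix
#' @param x a [genotype_matrix].
#' @param i integer or logical index over sites (kept in order).
#' @return a [genotype_matrix] with the selected sites.
#' @export
subset_sites <- function(x, i) {
  genotype_matrix(x$chrom[i], x$pos[i], x$ref[i], x$alt[i],
                  x$alleles[i, , drop = FALSE], x$sample_ids)
}

## equality used by round-trip tests
#' @method all.equal genotype_matrix
#' @export
all.equal.genotype_matrix <- function(target, current, ...) {
  for (f in c("chrom", "pos", "ref", "alt", "sample_ids")) {
    if (!identical(target[[f]], current[[f]]))
      return(sprintf("field '%s' differs", f))
  }
  if (!identical(unname(target$alleles), unname(current$alleles)))
    return("allele matrix differs")
  TRUE
}
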